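metricMatrix <- function(table, metric = c("strict", "relaxed",
                                           "mean_score")) {
  metric <- match.arg(metric)
  switch(metric,
         strict = successMatrix(table, "strict"),
         relaxed = successMatrix(table, "relaxed"),
         mean_score = scores(table))
}

#' Single best solver (SBS)
#'
#' The one solver with the highest mean performance over the benchmark
#' under the chosen metric — the static baseline any selector must beat.
#' Ties break to the earliest portfolio index.
#'
#' @param table a \code{\link{PerformanceTable}}.
#' @param metric \code{"strict"}, \code{"relaxed"} or \code{"mean_score"}.
#' @return list: \code{index}, \code{solverId}, \code{performance} (the
#'   column mean).
#' @export
singleBestSolver <- function(table, metric = "relaxed") {
  if (nrow(table) < 1L) stop("empty performance table")
  mu <- colMeans(metricMatrix(table, metric))
  i <- unname(argmaxFirst(mu))
  list(index = i, solverId = solverIds(portfolio(table))[i],
       performance = unname(mu[i]))
}

#' Virtual best solver (VBS) curve
#'
#' Per-instance oracle performance: the row maximum under the chosen
#' metric. The mean is the portfolio's performance ceiling.
#'
#' @inheritParams singleBestSolver
#' @return list: \code{perInstance}, \code{mean}.
#' @export
vbsCurve <- function(table, metric = "relaxed") {
  if (nrow(table) < 1L) stop("empty performance table")
  M <- metricMatrix(table, metric)
  v <- apply(M, 1, max)
  list(perInstance = v, mean = mean(v))
}

#' k-th best virtual selector (VBS at K)
#'
#' Per-instance k-th order statistic (descending) of the row: a virtual
#' selector that always picks each instance's k-th best solver. k = 1 is
#' the VBS; k = m the row minimum.
#'
#' @inheritParams singleBestSolver
#' @param k order statistic, 1 <= k <= m.
#' @return list: \code{perInstance}, \code{mean}.
#' @export
vbsAtK <- function(table, k, metric = "relaxed") {
  m <- ncol(table)
  if (k < 1 || k > m) stop("k must lie in 1..", m)
  M <- metricMatrix(table, metric)
  v <- apply(M, 1, function(r) sort(r, decreasing = TRUE)[k])
  list(perInstance = v, mean = mean(v))
}

#' k-th most frequently selected solver (Selected at K)
#'
#' Ranks solvers by how often the selector chose them; frequency ties
#' break to the earlier portfolio index.
#'
#' @param selections integer vector of selected solver indices.
#' @param k rank among the distinct selected solvers.
#' @param m portfolio size (defaults to the largest selected index).
#' @return list: \code{index}, \code{count}, \code{frequency}.
#' @export
selectedAtK <- function(selections, k, m = max(selections)) {
  counts <- tabulate(selections, nbins = m)
  nDistinct <- sum(counts > 0)
  if (k < 1 || k > nDistinct)
    stop("k = ", k, " exceeds the ", nDistinct, " distinct selected solvers")
  ord <- order(-counts, seq_len(m))
  i <- ord[k]
  list(index = i, count = counts[i],
       frequency = counts[i] / length(selections))
}

#' Fraction of the VBS-SBS gap closed
#'
#' \code{100 * (as - sbs) / (vbs - sbs)}: the share of the oracle's
#' headroom a selector captures. 0 means SBS-equivalent, 100 means
#' oracle-equivalent; negative values mean the selector widened the gap.
#' Degenerate benchmarks with VBS = SBS return \code{NA} with a warning.
#'
#' @param asPerf,sbsPerf,vbsPerf mean performances on a common scale.
#' @return percent, or \code{NA}.
#' @export
gapClosed <- function(asPerf, sbsPerf, vbsPerf) {
  if (vbsPerf < sbsPerf - 1e-12)
    stop("vbs < sbs: the oracle cannot underperform the single best solver")
  if (abs(vbsPerf - sbsPerf) < 1e-12) {
    warning("VBS equals SBS; gap closure undefined")
    return(NA_real_)
  }
  100 * (asPerf - sbsPerf) / (vbsPerf - sbsPerf)
}

#' Absolute improvement over the SBS in percentage points
#'
#' @param asPerf,sbsPerf success rates on the percent scale.
#' @return \code{asPerf - sbsPerf}.
#' @export
improvement <- function(asPerf, sbsPerf) asPerf - sbsPerf

## tie-corrected Kendall tau-b by explicit pair counting
kendallTauB <- function(x, y) {
  n <- length(x)
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  up <- upper.tri(sx)
  prod <- sx[up] * sy[up]
  C <- sum(prod > 0)
  D <- sum(prod < 0)
  n0 <- n * (n - 1) / 2
  n1 <- sum(sx[up] == 0)
  n2 <- sum(sy[up] == 0)
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

## average ranks descending (rank 1 = largest), for top-k set construction
## ties on means break to the earlier solver index
topKSets <- function(means) {
  ord <- order(-means, seq_along(means))
  lapply(seq_along(means), function(k) ord[seq_len(k)])
}

#' Rank-stability diagnostics between two protocols
#'
#' Compares the solver rankings induced by mean per-solver scores in two
#' performance tables over the same portfolio: Spearman's rho (average
#' ranks for ties), tie-corrected Kendall's tau-b, and the top-k Jaccard
#' overlaps J_k = |top_k(p) intersect top_k(q)| / |union| for k = 1..m
#' (top-k sets from descending means, ties to the earlier solver index),
#' with J1 the top-1 overlap and Jbar their mean. High rho with J1 = 0
#' signals protocols that agree globally but flip the best solver.
#'
#' @param tableP,tableQ \code{\link{PerformanceTable}}s over identical
#'   portfolios.
#' @param metric \code{"mean_score"} (default: composite scores, as used
#'   in the reported diagnostics) or a success criterion.
#' @return list: \code{spearman}, \code{kendallTauB}, \code{j1},
#'   \code{jbar}, \code{jkCurve}, \code{meansP}, \code{meansQ}.
#' @export
rankStability <- function(tableP, tableQ, metric = "mean_score") {
  if (!identical(solverIds(portfolio(tableP)),
                 solverIds(portfolio(tableQ))))
    stop("tables must share an identical portfolio (same solvers, same order)")
  mp <- colMeans(metricMatrix(tableP, metric))
  mq <- colMeans(metricMatrix(tableQ, metric))
  rp <- rank(mp)                        # average ranks on ties
  rq <- rank(mq)
  spearman <- if (stats::sd(rp) == 0 || stats::sd(rq) == 0) NA_real_
              else as.numeric(stats::cor(rp, rq))
  tauB <- kendallTauB(mp, mq)
  sp <- topKSets(mp)
  sq <- topKSets(mq)
  jk <- vapply(seq_along(mp), function(k) {
    a <- sp[[k]]; b <- sq[[k]]
    length(intersect(a, b)) / length(union(a, b))
  }, 0)
  list(spearman = spearman, kendallTauB = tauB, j1 = jk[1],
       jbar = mean(jk), jkCurve = jk, meansP = mp, meansQ = mq)
}

#' Oracle-winner entropy of a benchmark
#'
#' Shannon entropy (base 2) of the distribution of per-instance oracle
#' winners under the composite score, with exact ties splitting their mass
#' fractionally among the tied maxima. 0 bits means a single solver
#' dominates every instance (no selection headroom); log2(m) bits means a
#' uniform winner distribution.
#'
#' @param table a \code{\link{PerformanceTable}}.
#' @return entropy in bits.
#' @export
vbsEntropy <- function(table) {
  if (nrow(table) < 1L) stop("empty performance table")
  S <- scores(table)
  w <- numeric(ncol(S))
  for (i in seq_len(nrow(S))) {
    winners <- which(S[i, ] == max(S[i, ]))
    w[winners] <- w[winners] + 1 / length(winners)
  }
  p <- w / sum(w)
  p <- p[p > 0]
  -sum(p * log2(p))
}

## which selections attain the row maximum (any tied maximum counts)
oracleAgreement <- function(selections, scoreMatrix) {
  vapply(seq_along(selections), function(i) {
    r <- scoreMatrix[i, ]
    r[selections[i]] >= max(r) - 1e-12
  }, TRUE)
}

#' Margin-based reliability diagnostics
#'
#' Sorts predictions by margin (top-1 minus top-2 predicted probability),
#' splits them into equal-mass bins (remainder instances absorbed by the
#' lowest-margin bins) and reports, per bin, the probability that the
#' selected solver attains the oracle score, and the probabilities that
#' the selected solver's composite score strictly exceeds / at least
#' equals the SBS solver's score.
#'
#' @param selections integer solver indices, aligned with the table rows.
#' @param margins numeric margins, same length.
#' @param table a \code{\link{PerformanceTable}}.
#' @param nBins number of equal-mass bins (default 12).
#' @param sbsMetric metric used to identify the SBS column.
#' @return data.frame with one row per bin: mean margin, reliability,
#'   P(s_sel > s_SBS), P(s_sel >= s_SBS), bin size.
#' @export
marginReliability <- function(selections, margins, table, nBins = 12L,
                              sbsMetric = "mean_score") {
  n <- nrow(table)
  if (length(selections) != n || length(margins) != n)
    stop("predictions must align with the table rows")
  if (n < nBins) stop("need at least nBins instances")
  S <- scores(table)
  sbs <- singleBestSolver(table, sbsMetric)$index
  ord <- order(margins)
  base <- n %/% nBins
  extra <- n %% nBins
  sizes <- rep(base, nBins) + c(rep(1L, extra), rep(0L, nBins - extra))
  stopifnot(sum(sizes) == n)
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  agree <- oracleAgreement(selections, S)
  sSel <- S[cbind(seq_len(n), selections)]
  sSbs <- S[, sbs]
  out <- lapply(seq_len(nBins), function(b) {
    idx <- ord[starts[b]:ends[b]]
    data.frame(bin = b, n = length(idx), meanMargin = mean(margins[idx]),
               reliability = mean(agree[idx]),
               pBeatSbs = mean(sSel[idx] > sSbs[idx]),
               pAtLeastSbs = mean(sSel[idx] >= sSbs[idx]))
  })
  do.call(rbind, out)
}

#' Selection-distribution diagnostics
#'
#' For the selector's \code{top} most frequently chosen solvers, reports
#' the selector's selection frequencies, the oracle-winner frequencies of
#' the same solvers (ties split fractionally), their realised relaxed
#' success rates, and the overall top-1 oracle agreement rate. A selector
#' concentrating far more mass than the oracle on one solver indicates
#' selection collapse.
#'
#' @param selections integer solver indices aligned with the table rows.
#' @param table a \code{\link{PerformanceTable}}.
#' @param top number of solvers to report.
#' @return list: \code{perSolver} data.frame, \code{agreementRate},
#'   \code{selectorFreqAll} (full frequency vector, sums to 1).
#' @export
selectionDistribution <- function(selections, table, top = 3L) {
  n <- nrow(table)
  m <- ncol(table)
  S <- scores(table)
  selFreq <- tabulate(selections, nbins = m) / n
  w <- numeric(m)
  for (i in seq_len(n)) {
    winners <- which(S[i, ] == max(S[i, ]))
    w[winners] <- w[winners] + 1 / length(winners)
  }
  oracleFreq <- w / n
  succ <- colMeans(successMatrix(table, "relaxed"))
  ord <- order(-selFreq, seq_len(m))
  sel <- ord[seq_len(min(top, m))]
  list(perSolver = data.frame(
         index = sel, solverId = solverIds(portfolio(table))[sel],
         selectorFreq = selFreq[sel], oracleFreq = oracleFreq[sel],
         relaxedSuccess = succ[sel]),
       agreementRate = mean(oracleAgreement(selections, S)),
       selectorFreqAll = selFreq)
}

#' Assemble the full evaluation report for a selector
#'
#' Computes, under both success criteria: SBS / selector / VBS success
#' rates, gap closures, and the paired sign test between the selector's
#' and the SBS's per-instance successes, plus selection frequencies.
#' \code{selections} may come from out-of-fold cross-validation
#' (\code{\link{crossValidateSelector}}) or a cross-benchmark run; in the
#' latter case the caller guarantees the training portfolio matched.
#'
#' @param selections integer solver indices aligned with the table rows.
#' @param table a \code{\link{PerformanceTable}}.
#' @return list of class \code{"EvalReport"}.
#' @export
evaluateSelections <- function(selections, table) {
  n <- nrow(table)
  if (length(selections) != n)
    stop("selections must align with the table rows")
  out <- list()
  for (crit in c("strict", "relaxed")) {
    M <- successMatrix(table, crit)
    sbs <- singleBestSolver(table, crit)
    vbs <- vbsCurve(table, crit)
    selSucc <- M[cbind(seq_len(n), selections)]
    asPerf <- mean(selSucc)
    gc <- if (abs(vbs$mean - sbs$performance) < 1e-12) NA_real_
          else 100 * (asPerf - sbs$performance) /
            (vbs$mean - sbs$performance)
    out[[crit]] <- list(
      sbs = sbs$performance, selector = asPerf, vbs = vbs$mean,
      sbsSolver = sbs$solverId, gapClosedPercent = gc,
      pValue = pairedSignTest(selSucc, M[, sbs$index]))
  }
  out$selectionFrequencies <-
    tabulate(selections, nbins = ncol(table)) / n
  names(out$selectionFrequencies) <- solverIds(portfolio(table))
  class(out) <- "EvalReport"
  out
}

#' @export
print.EvalReport <- function(x, ...) {
  for (crit in c("strict", "relaxed")) {
    r <- x[[crit]]
    cat(sprintf(
      "%-8s SBS %.4f (%s) | selector %.4f | VBS %.4f | gap closed %s%% | p = %.3g\n",
      crit, r$sbs, r$sbsSolver, r$selector, r$vbs,
      if (is.na(r$gapClosedPercent)) "NA"
      else sprintf("%.2f", r$gapClosedPercent), r$pValue))
  }
  invisible(x)
}
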