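#' Instances-by-solvers performance table
#'
#' A \code{SummarizedExperiment} subclass holding the per-instance,
#' per-solver pose evaluations of a benchmark: raw RMSD and PoseBusters
#' flags, the derived gated composite scores, strict/relaxed success labels,
#' and a missingness mask. Rows are complexes (instances), columns are
#' portfolio solvers; \code{colData} carries the solver configurations.
#'
#' Cells with no recorded pose (engine failure on a complex) carry
#' \code{NA} RMSD/PB, composite score 0 and success 0 — a solver that
#' produces no pose cannot succeed — with the mask retained for sensitivity
#' analyses.
#'
#' @aliases PerformanceTable-class
#' @exportClass PerformanceTable
setClass("PerformanceTable",
         contains = "SummarizedExperiment",
         representation(scoring = "ScoringConfig"))

setValidity("PerformanceTable", function(object) {
  msg <- character()
  need <- c("rmsd", "pbValid", "score", "successStrict", "successRelaxed",
            "missing")
  have <- SummarizedExperiment::assayNames(object)
  if (!all(need %in% have))
    return(paste("missing assays:", paste(setdiff(need, have), collapse = ", ")))
  sc <- SummarizedExperiment::assay(object, "score")
  if (length(sc) && (min(sc) < 0 || max(sc) > 1))
    msg <- c(msg, "scores must lie in [0, 1]")
  ss <- SummarizedExperiment::assay(object, "successStrict")
  sr <- SummarizedExperiment::assay(object, "successRelaxed")
  if (length(ss) && any(ss > sr))
    msg <- c(msg, "strict success must imply relaxed success")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("solverId", "baseName", "postprocess") %in% colnames(cd)))
    msg <- c(msg, "colData must carry solverId, baseName, postprocess")
  if (length(msg)) msg else TRUE
})

#' @param rmsd numeric matrix (instances x solvers), Angstrom; \code{NA}
#'   marks missing cells.
#' @param pbValid logical/0-1 matrix, same shape; \code{NA} only where
#'   \code{rmsd} is \code{NA}.
#' @param portfolio a \code{\link{Portfolio}} whose size matches
#'   \code{ncol(rmsd)}.
#' @param scoring a \code{\link{ScoringConfig}}.
#' @return a \code{PerformanceTable}.
#' @rdname PerformanceTable-class
#' @export
PerformanceTable <- function(rmsd, pbValid, portfolio,
                             scoring = ScoringConfig()) {
  stopifnot(is.matrix(rmsd), is(portfolio, "Portfolio"))
  pbValid <- matrix(as.integer(pbValid), nrow(rmsd), ncol(rmsd),
                    dimnames = dimnames(rmsd))
  if (ncol(rmsd) != nSolvers(portfolio))
    stop("rmsd has ", ncol(rmsd), " columns but the portfolio has ",
         nSolvers(portfolio), " solvers")
  miss <- is.na(rmsd)
  if (any(is.na(pbValid) != miss))
    stop("pbValid must be missing exactly where rmsd is missing")
  score <- matrix(0, nrow(rmsd), ncol(rmsd))
  ss <- sr <- matrix(0L, nrow(rmsd), ncol(rmsd))
  if (any(!miss)) {
    ok <- !miss
    score[ok] <- compositeScore(rmsd[ok], pbValid[ok], scoring)
    ss[ok] <- successLabel(rmsd[ok], pbValid[ok], "strict", scoring)
    sr[ok] <- successLabel(rmsd[ok], pbValid[ok], "relaxed", scoring)
  }
  ids <- rownames(rmsd)
  if (is.null(ids)) ids <- sprintf("instance_%d", seq_len(nrow(rmsd)))
  dn <- list(ids, solverIds(portfolio))
  dimnames(rmsd) <- dimnames(pbValid) <- dimnames(score) <-
    dimnames(ss) <- dimnames(sr) <- dimnames(miss) <- dn
  cd <- S4Vectors::DataFrame(solverId = solverIds(portfolio),
                             baseName = portfolio@baseNames,
                             postprocess = portfolio@postprocess,
                             row.names = solverIds(portfolio))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rmsd = rmsd, pbValid = pbValid, score = score,
                  successStrict = ss, successRelaxed = sr, missing = miss),
    colData = cd)
  new("PerformanceTable", se, scoring = scoring)
}

#' @rdname PerformanceTable-class
#' @export
setMethod("scores", "PerformanceTable",
          function(x) SummarizedExperiment::assay(x, "score"))

#' @rdname PerformanceTable-class
#' @export
setMethod("successMatrix", "PerformanceTable",
  function(x, criterion = c("strict", "relaxed")) {
    criterion <- match.arg(criterion)
    SummarizedExperiment::assay(
      x, if (criterion == "strict") "successStrict" else "successRelaxed")
  })

#' @rdname PerformanceTable-class
#' @export
setMethod("missingMask", "PerformanceTable",
          function(x) SummarizedExperiment::assay(x, "missing"))

#' @rdname PerformanceTable-class
#' @export
setMethod("portfolio", "PerformanceTable", function(x) {
  cd <- SummarizedExperiment::colData(x)
  Portfolio(baseNames = cd$baseName, postprocess = cd$postprocess,
            solverIds = cd$solverId)
})

#' @rdname PerformanceTable-class
#' @export
setMethod("instanceIds", "PerformanceTable", function(x) rownames(x))

#' @rdname PerformanceTable-class
#' @export
setMethod("scoringConfig", "PerformanceTable", function(x) x@scoring)

setMethod("show", "PerformanceTable", function(object) {
  cat("PerformanceTable:", nrow(object), "instances x", ncol(object),
      "solvers\n")
  cat("  missing cells:", sum(missingMask(object)), "\n")
  cat("  mean relaxed success per solver:",
      paste(sprintf("%.3f", colMeans(successMatrix(object, "relaxed"))),
            collapse = " "), "\n")
})

#' Read a pose-evaluation CSV into a PerformanceTable
#'
#' The CSV schema is \code{instance_id,solver_id,postprocess,rmsd,pb_valid}
#' with \code{pb_valid} coded 0/1. Every (instance, solver) pair may appear
#' at most once; rows naming a solver absent from the portfolio are an
#' error; pairs absent from the file become missing cells (score 0,
#' flagged in the mask).
#'
#' @param csvPath path to the CSV file.
#' @param portfolio a \code{\link{Portfolio}}.
#' @param scoring a \code{\link{ScoringConfig}}.
#' @return a \code{\link{PerformanceTable}}.
#' @export
loadPerformanceTable <- function(csvPath, portfolio,
                                 scoring = ScoringConfig()) {
  df <- read.csv(csvPath, stringsAsFactors = FALSE)
  need <- c("instance_id", "solver_id", "rmsd", "pb_valid")
  if (!all(need %in% names(df)))
    stop("pose-evaluation CSV must have columns ",
         paste(need, collapse = ", "))
  unknown <- setdiff(unique(df$solver_id), solverIds(portfolio))
  if (length(unknown))
    stop("solver(s) not in portfolio: ", paste(unknown, collapse = ", "))
  key <- paste(df$instance_id, df$solver_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (instance, solver) rows in ", csvPath)
  ids <- unique(df$instance_id)
  m <- nSolvers(portfolio)
  rmsd <- matrix(NA_real_, length(ids), m,
                 dimnames = list(ids, solverIds(portfolio)))
  pb <- matrix(NA_integer_, length(ids), m,
               dimnames = list(ids, solverIds(portfolio)))
  ri <- match(df$instance_id, ids)
  ci <- match(df$solver_id, solverIds(portfolio))
  rmsd[cbind(ri, ci)] <- df$rmsd
  pb[cbind(ri, ci)] <- as.integer(df$pb_valid)
  PerformanceTable(rmsd, pb, portfolio, scoring)
}

#' Write a PerformanceTable back to the pose-evaluation CSV schema
#'
#' Only non-missing cells are written; loading the file with the same
#' portfolio and scoring configuration reproduces the table exactly.
#'
#' @param table a \code{\link{PerformanceTable}}.
#' @param csvPath output path.
#' @return \code{csvPath}, invisibly.
#' @export
savePerformanceTable <- function(table, csvPath) {
  miss <- missingMask(table)
  idx <- which(!miss, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  cd <- SummarizedExperiment::colData(table)
  df <- data.frame(
    instance_id = rownames(table)[idx[, 1]],
    solver_id = cd$solverId[idx[, 2]],
    postprocess = cd$postprocess[idx[, 2]],
    ## %.17g guarantees the double survives the text round trip exactly
    rmsd = sprintf("%.17g", SummarizedExperiment::assay(table, "rmsd")[idx]),
    pb_valid = SummarizedExperiment::assay(table, "pbValid")[idx])
  write.csv(df, csvPath, row.names = FALSE, quote = FALSE)
  invisible(csvPath)
}

#' Remove blocklisted instances from a table
#'
#' Drops every instance whose id appears in the blocklist (the mechanism
#' used to exclude training-corpus overlaps such as PDBBind v2020 or
#' DockGen protein lists from an evaluation split).
#'
#' @param table a \code{\link{PerformanceTable}}.
#' @param blocklist character vector of instance ids.
#' @return the restricted \code{PerformanceTable}; warns if nothing remains.
#' @export
applyBlocklist <- function(table, blocklist) {
  keep <- !(rownames(table) %in% blocklist)
  removed <- sum(!keep)
  if (!any(keep))
    warning("blocklist removed all ", removed, " instances")
  message(removed, " instance(s) removed by blocklist")
  table[keep, ]
}

#' Deterministic k-fold split of instance ids
#'
#' Shuffles ids with the given seed and assigns folds round-robin, so fold
#' sizes differ by at most one. With k = 5 each fold serves once as the 20
#' percent test set of an 80-20 split.
#'
#' @param instanceIds character vector.
#' @param k number of folds (>= 2).
#' @param seed integer seed; the same seed reproduces the same split.
#' @return named integer vector of fold indices in \code{0:(k-1)}.
#' @export
makeKFold <- function(instanceIds, k = 5L, seed = 1L) {
  n <- length(instanceIds)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("need at least k instances (n = ", n, ", k = ", k, ")")
  perm <- withLocalSeed(seed, sample.int(n))
  folds <- integer(n)
  folds[perm] <- (seq_len(n) - 1L) %% as.integer(k)
  names(folds) <- instanceIds
  attr(folds, "seed") <- as.integer(seed)
  attr(folds, "k") <- as.integer(k)
  folds
}
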