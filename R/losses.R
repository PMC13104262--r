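#' Binary cross-entropy with logits
#'
#' Multi-label calibration loss for bounded composite-score targets,
#' \deqn{-\sum_a [ s_a \log\sigma(z_a) + (1-s_a)\log(1-\sigma(z_a)) ],}
#' computed in the numerically stable softplus form
#' \eqn{\sum_a [\mathrm{log1pexp}(z_a) - s_a z_a]}. Outputs are modelled
#' independently per solver (no softmax competition), so soft labels in
#' [0, 1] are supported.
#'
#' @param logits numeric vector.
#' @param targets numeric vector in [0, 1], same length.
#' @return non-negative scalar (sum over solvers).
#' @export
bceLoss <- function(logits, targets) {
  if (length(logits) != length(targets)) stop("shape mismatch")
  if (anyNA(targets) || any(targets < 0 | targets > 1))
    stop("targets must lie in [0, 1]")
  sum(log1pexp(logits) - targets * logits)
}

bceGrad <- function(logits, targets) sigmoid(logits) - targets

#' Mean squared error between predicted probabilities and targets
#'
#' @param probs numeric vector (e.g. sigmoid of logits).
#' @param targets numeric vector, same length.
#' @return non-negative scalar (mean over elements).
#' @export
mseLoss <- function(probs, targets) {
  if (length(probs) != length(targets)) stop("shape mismatch")
  mean((probs - targets)^2)
}

## gradient wrt logits, probs = sigmoid(logits)
mseGradLogits <- function(logits, targets) {
  p <- sigmoid(logits)
  2 * (p - targets) * p * (1 - p) / length(logits)
}

#' Pairwise logistic ranking loss
#'
#' Mean over ordered solver pairs (a, b) with
#' \code{targets[a] > targets[b] + tieTol} of
#' \eqn{\log(1 + \exp(-(z_a - z_b)))}. Pairs tied within \code{tieTol} are
#' excluded; with no valid pair the loss is 0 (with a warning).
#'
#' @param logits numeric vector, length >= 2.
#' @param targets numeric vector, same length.
#' @param tieTol tie tolerance on the target scale.
#' @param warn warn when no valid pair exists.
#' @return non-negative scalar.
#' @export
pairwiseLogisticLoss <- function(logits, targets, tieTol = 1e-6,
                                 warn = TRUE) {
  if (length(logits) < 2L) stop("need at least 2 solvers")
  if (length(logits) != length(targets)) stop("shape mismatch")
  d <- outer(targets, targets, "-")
  valid <- d > tieTol
  if (!any(valid)) {
    if (warn) warning("no target pairs outside the tie tolerance; loss = 0")
    return(0)
  }
  zd <- outer(logits, logits, "-")
  mean(log1pexp(-zd[valid]))
}

pairwiseLogisticGrad <- function(logits, targets, tieTol = 1e-6) {
  m <- length(logits)
  d <- outer(targets, targets, "-")
  valid <- d > tieTol
  g <- numeric(m)
  if (!any(valid)) return(g)
  np <- sum(valid)
  zd <- outer(logits, logits, "-")
  w <- -sigmoid(-zd) / np              # d/d(z_a - z_b) of log1pexp(-(za-zb))
  w[!valid] <- 0
  rowSums(w) - colSums(w)
}

#' Exact NDCG at k
#'
#' Discounted cumulative gain of the top-k solvers by predicted logits
#' (gains = targets, discount 1/log2(1 + rank)), normalised by the ideal
#' DCG. Returns 1 when every ordering is ideal (uniform gains) or when the
#' predicted order matches the target order on the top-k.
#'
#' @param logits,targets numeric vectors.
#' @param k truncation depth.
#' @return value in [0, 1].
#' @export
exactNdcg <- function(logits, targets, k = 3L) {
  if (length(logits) < k) stop("need at least k solvers")
  disc <- 1 / log2(1 + seq_len(k))
  ord <- order(-logits, seq_along(logits))
  dcg <- sum(targets[ord[seq_len(k)]] * disc)
  idcg <- sum(sort(targets, decreasing = TRUE)[seq_len(k)] * disc)
  if (idcg == 0) return(1)
  dcg / idcg
}

softRanks <- function(logits, temperature) {
  zd <- outer(logits, logits, "-") / temperature   # zd[b, a] pattern below
  ## rank_a = 1 + sum_{b != a} sigma((z_b - z_a)/T)
  S <- sigmoid(-zd)                    # S[a, b] = sigma((z_b - z_a)/T)
  diag(S) <- 0
  1 + rowSums(S)
}

#' Smooth NDCG at 3 surrogate loss
#'
#' One minus an approximate NDCG at 3 built from temperature-parameterised
#' soft ranks: each solver's rank is the sum of pairwise sigmoids, its
#' top-k membership a sigmoid of (k + 1/2 - rank), and the discount the
#' usual 1/log2(1 + rank) evaluated at the soft rank. As the temperature
#' approaches 0 the surrogate approaches 1 - exact NDCG at 3. Uniform
#' targets give loss 0 (any order is ideal).
#'
#' @param logits,targets numeric vectors, length >= 3.
#' @param temperature softness of the rank surrogate.
#' @param k truncation depth (default 3).
#' @return value in [0, 1].
#' @export
ndcg3Loss <- function(logits, targets, temperature = 1, k = 3L) {
  if (length(logits) < k) stop("need at least k solvers")
  if (length(logits) != length(targets)) stop("shape mismatch")
  if (max(targets) - min(targets) < 1e-12) return(0)
  disc <- 1 / log2(1 + seq_len(k))
  idcg <- sum(sort(targets, decreasing = TRUE)[seq_len(k)] * disc)
  r <- softRanks(logits, temperature)
  w <- sigmoid((k + 0.5 - r) / temperature)
  dcg <- sum(targets * w / log2(1 + r))
  max(0, min(1, 1 - dcg / idcg))
}

ndcg3Grad <- function(logits, targets, temperature = 1, k = 3L) {
  m <- length(logits)
  if (max(targets) - min(targets) < 1e-12) return(numeric(m))
  disc <- 1 / log2(1 + seq_len(k))
  idcg <- sum(sort(targets, decreasing = TRUE)[seq_len(k)] * disc)
  r <- softRanks(logits, temperature)
  ## clamp only affects gradient when saturated; recompute raw loss
  w <- sigmoid((k + 0.5 - r) / temperature)
  raw <- 1 - sum(targets * w / log2(1 + r)) / idcg
  if (raw <= 0 || raw >= 1) return(numeric(m))
  l2 <- log2(1 + r)
  dw <- -w * (1 - w) / temperature                   # dw/dr
  dDdr <- targets * (dw / l2 - w / (l2^2 * (1 + r) * log(2)))
  dLdr <- -dDdr / idcg
  ## dr_a/dz_c: sig' terms of the pairwise matrix
  zd <- outer(logits, logits, "-") / temperature
  Sp <- sigmoid(-zd) * (1 - sigmoid(-zd)) / temperature
  diag(Sp) <- 0
  ## dr_a/dz_b = Sp[a, b] (b != a); dr_a/dz_a = -sum_b Sp[a, b]
  g <- as.vector(t(Sp) %*% dLdr) - dLdr * rowSums(Sp)
  g
}

#' Exact two-sided sign test for paired binary outcomes
#'
#' Compares per-instance success indicators of a selector and the single
#' best solver. Only discordant pairs inform the test; the p-value is the
#' exact two-sided binomial tail at p = 1/2, and 1.0 when there are no
#' discordant pairs.
#'
#' @param successA,successB binary vectors of equal length.
#' @return p-value in [0, 1].
#' @export
pairedSignTest <- function(successA, successB) {
  if (length(successA) != length(successB)) stop("length mismatch")
  if (length(successA) < 1L) stop("need at least one pair")
  nAB <- sum(successA == 1 & successB == 0)
  nBA <- sum(successA == 0 & successB == 1)
  nd <- nAB + nBA
  if (nd == 0) return(1.0)
  k <- min(nAB, nBA)
  min(1, 2 * stats::pbinom(k, nd, 0.5))
}

## weighted loss mix over a batch of logits/targets matrices; returns the
## scalar loss and the gradient wrt logits (both already batch-averaged)
batchLossAndGrad <- function(logits, targets, mix, tieTol = 1e-6,
                             ndcgTemp = 1) {
  B <- nrow(logits)
  loss <- 0
  grad <- matrix(0, nrow(logits), ncol(logits))
  if (mix["bce"] > 0) {
    l <- sum(log1pexp(logits) - targets * logits) / B
    loss <- loss + mix["bce"] * l
    grad <- grad + mix["bce"] * (sigmoid(logits) - targets) / B
  }
  if (mix["mse"] > 0) {
    p <- sigmoid(logits)
    loss <- loss + mix["mse"] * mean((p - targets)^2)
    grad <- grad + mix["mse"] * 2 * (p - targets) * p * (1 - p) /
      length(logits)
  }
  if (mix["pairwise"] > 0) {
    for (i in seq_len(B)) {
      loss <- loss + mix["pairwise"] *
        pairwiseLogisticLoss(logits[i, ], targets[i, ], tieTol,
                             warn = FALSE) / B
      grad[i, ] <- grad[i, ] + mix["pairwise"] *
        pairwiseLogisticGrad(logits[i, ], targets[i, ], tieTol) / B
    }
  }
  if (mix["ndcg3"] > 0) {
    for (i in seq_len(B)) {
      loss <- loss + mix["ndcg3"] *
        ndcg3Loss(logits[i, ], targets[i, ], ndcgTemp) / B
      grad[i, ] <- grad[i, ] + mix["ndcg3"] *
        ndcg3Grad(logits[i, ], targets[i, ], ndcgTemp) / B
    }
  }
  list(loss = as.numeric(loss), grad = grad)
}
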