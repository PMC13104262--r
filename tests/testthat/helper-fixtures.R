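## shared in-code fixtures and independent oracles

## build a PerformanceTable directly from an rmsd matrix (pb all-pass by
## default); solver count inferred from columns
makeTable <- function(rmsd, pb = NULL, lambda = 3) {
  if (is.null(dim(rmsd))) rmsd <- matrix(rmsd, nrow = 1)
  if (is.null(pb)) pb <- matrix(1L, nrow(rmsd), ncol(rmsd))
  pf <- Portfolio(sprintf("s%d", seq_len(ncol(rmsd))))
  PerformanceTable(rmsd, pb, pf, ScoringConfig(lambda = lambda))
}

## random table with occasional exact ties between solver columns
randomTable <- function(n, m, seed, tieProb = 0.2) {
  set.seed(seed)
  rmsd <- matrix(runif(n * m, 0, 6), n, m)
  if (runif(1) < tieProb && m >= 2) rmsd[, 2] <- rmsd[, 1]
  pb <- matrix(rbinom(n * m, 1, 0.8), n, m)
  makeTable(rmsd, pb)
}

## naive pair-counting Kendall tau-b (independent of the package's
## vectorised sign-matrix implementation)
naiveTauB <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (sign(dx) == sign(dy)) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## central-difference gradient of f at x
numGrad <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, 0)
}

## small instance set with seeded random embeddings
randomInstances <- function(n, dP = 8, dL = 4, seed = 1) {
  set.seed(seed)
  ids <- sprintf("i%03d", seq_len(n))
  prot <- lapply(seq_len(n), function(i)
    matrix(rnorm(sample(2:6, 1) * dP), ncol = dP))
  lig <- matrix(rnorm(n * dL), n, dL)
  InstanceSet(ids, prot, lig)
}

## tiny selector for architecture tests
tinyModel <- function(seed = 42, nHeads = 2, mOut = 3) {
  newSelector(selectorConfig(dProtein = 8, dLigand = 4, nHeads = nHeads,
                             jointDim = 5, nBlocks = 2, blockWidth = 7,
                             mOut = mOut, seed = seed))
}

## zero out every weight in a model (biases stay modifiable by caller)
zeroParams <- function(model) {
  model@params <- rapply(model@params, function(x) x * 0, how = "replace")
  ## batch-norm gammas back to 1 so inference stays well defined
  for (k in seq_along(model@params$blocks))
    model@params$blocks[[k]]$gamma <-
      model@params$blocks[[k]]$gamma * 0 + 1
  model
}
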