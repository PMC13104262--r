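#' @importFrom methods new validObject is slot show
#' @importFrom stats cor pnorm qnorm rnorm runif rbinom setNames
#' @importFrom utils read.csv write.csv head modifyList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
NULL

## numerically stable log(1 + exp(x)); the cutovers follow the standard
## Maechler decomposition so the function is exact in double precision
log1pexp <- function(x) {
  out <- x
  i1 <- x <= -37
  i2 <- x > -37 & x <= 18
  i3 <- x > 18 & x <= 33.3
  i4 <- x > 33.3
  out[i1] <- exp(x[i1])
  out[i2] <- log1p(exp(x[i2]))
  out[i3] <- x[i3] + exp(-x[i3])
  out[i4] <- x[i4]
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## run code under a temporary RNG state; restores the caller's stream
withLocalSeed <- function(seed, code) {
  if (!is.null(old <- globalenv()$.Random.seed)) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

stopifnotScalarNumber <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(what, " must be a single finite number", call. = FALSE)
  invisible(x)
}

## argmax with ties broken to the earliest index (portfolio order is the
## documented tie-break priority everywhere in the package)
argmaxFirst <- function(x) which.max(x)
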