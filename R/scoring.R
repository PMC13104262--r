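#' Scoring configuration for gated composite pose scores
#'
#' Holds the parameters of the composite pose score used throughout the
#' package: the steepness \code{lambda} of the sigmoid RMSD score, its centre
#' (2 Angstrom, where the maximum gradient occurs), and the strict / relaxed
#' success thresholds (1 and 2 Angstrom; both criteria additionally require
#' PoseBusters validity).
#'
#' @slot lambda positive real; sensitivity of the RMSD score (unitless).
#' @slot center positive real; centre of the sigmoid in Angstrom.
#' @slot strictThreshold real, Angstrom; strict success RMSD cutoff.
#' @slot relaxedThreshold real, Angstrom; relaxed success RMSD cutoff.
#' @aliases ScoringConfig-class
#' @exportClass ScoringConfig
setClass("ScoringConfig",
  representation(lambda = "numeric", center = "numeric",
                 strictThreshold = "numeric", relaxedThreshold = "numeric"),
  prototype(lambda = 3, center = 2, strictThreshold = 1, relaxedThreshold = 2))

setValidity("ScoringConfig", function(object) {
  msg <- character()
  if (length(object@lambda) != 1L || !is.finite(object@lambda) ||
      object@lambda <= 0)
    msg <- c(msg, "lambda must be a single positive finite number")
  if (length(object@center) != 1L || !is.finite(object@center) ||
      object@center <= 0)
    msg <- c(msg, "center must be a single positive finite number")
  if (object@strictThreshold >= object@relaxedThreshold)
    msg <- c(msg, "strictThreshold must be < relaxedThreshold")
  if (length(msg)) msg else TRUE
})

#' @param lambda,center,strictThreshold,relaxedThreshold see slots.
#' @return a \code{ScoringConfig} object.
#' @examples
#' cfg <- ScoringConfig(lambda = 3)
#' rmsdScore(c(0, 2, 4), cfg)
#' @rdname ScoringConfig-class
#' @export
ScoringConfig <- function(lambda = 3, center = 2,
                          strictThreshold = 1, relaxedThreshold = 2) {
  new("ScoringConfig", lambda = lambda, center = center,
      strictThreshold = strictThreshold, relaxedThreshold = relaxedThreshold)
}

setMethod("show", "ScoringConfig", function(object) {
  cat("ScoringConfig: lambda =", object@lambda,
      "| center =", object@center, "A",
      "| strict <=", object@strictThreshold, "A",
      "| relaxed <=", object@relaxedThreshold, "A\n")
})

#' Sigmoid RMSD score
#'
#' Smooth, strictly decreasing score of pose RMSD,
#' \deqn{s(x; \lambda) = \frac{1 + e^{-\lambda c}}{1 + e^{\lambda (x - c)}}}
#' with centre \eqn{c} (default 2 Angstrom, the conventional geometric
#' validity threshold, where the gradient magnitude is maximal) so that
#' \eqn{s(0) = 1} exactly. Unlike hard-threshold scores it never clips to
#' zero, so moderately poor poses remain ordered.
#'
#' @param rmsd non-negative numeric vector, Angstrom.
#' @param config a \code{\link{ScoringConfig}}.
#' @return numeric vector in (0, 1].
#' @export
rmsdScore <- function(rmsd, config = ScoringConfig()) {
  stopifnot(is(config, "ScoringConfig"))
  validObject(config)
  if (!is.numeric(rmsd) || anyNA(rmsd) || any(rmsd < 0))
    stop("rmsd must be non-negative and non-missing", call. = FALSE)
  lam <- config@lambda
  cen <- config@center
  ## numerator/denominator in log space for large lambda*(x - c)
  exp(log1p(exp(-lam * cen)) - log1pexp(lam * (rmsd - cen)))
}

#' PoseBusters validity gate
#'
#' Maps the precomputed PoseBusters pass/fail flag (pass = all 18 physical
#' plausibility checks passed) to 1/0. A missing flag is a hard error: it is
#' never silently treated as a pass or a fail.
#'
#' @param pbValid logical (or 0/1) vector.
#' @return integer vector of 0/1.
#' @export
pbGate <- function(pbValid) {
  if (is.null(pbValid) || length(pbValid) == 0L)
    stop("PB-validity flag is missing", call. = FALSE)
  if (anyNA(pbValid))
    stop("PB-validity flag contains missing values; ",
         "missing flags must be resolved upstream", call. = FALSE)
  if (is.numeric(pbValid)) {
    if (!all(pbValid %in% c(0, 1)))
      stop("numeric PB flags must be 0/1", call. = FALSE)
    return(as.integer(pbValid))
  }
  if (!is.logical(pbValid))
    stop("pbValid must be logical or 0/1", call. = FALSE)
  as.integer(pbValid)
}

#' Gated composite pose score
#'
#' The sigmoid RMSD score multiplied by the PoseBusters gate: a pose that
#' fails any plausibility check scores exactly 0 regardless of its RMSD, so
#' no geometrically close but chemically impossible pose can receive a
#' decent score. This is both the supervision target and the evaluation
#' currency of the package.
#'
#' @param rmsd non-negative numeric vector, Angstrom.
#' @param pbValid logical (or 0/1) vector, recycled against \code{rmsd}.
#' @param config a \code{\link{ScoringConfig}}.
#' @return numeric vector in [0, 1].
#' @export
compositeScore <- function(rmsd, pbValid, config = ScoringConfig()) {
  rmsdScore(rmsd, config) * pbGate(pbValid)
}

#' Binary pose success under the strict or relaxed criterion
#'
#' Strict success: RMSD <= 1 Angstrom and PB-valid; relaxed success:
#' RMSD <= 2 Angstrom and PB-valid. Thresholds are inclusive.
#'
#' @param rmsd non-negative numeric vector, Angstrom.
#' @param pbValid logical (or 0/1) vector.
#' @param criterion \code{"strict"} or \code{"relaxed"}.
#' @param config a \code{\link{ScoringConfig}} carrying the thresholds.
#' @return integer vector of 0/1.
#' @export
successLabel <- function(rmsd, pbValid, criterion = c("strict", "relaxed"),
                         config = ScoringConfig()) {
  criterion <- match.arg(criterion)
  if (!is.numeric(rmsd) || anyNA(rmsd) || any(rmsd < 0))
    stop("rmsd must be non-negative and non-missing", call. = FALSE)
  thr <- if (criterion == "strict") config@strictThreshold
         else config@relaxedThreshold
  as.integer(rmsd <= thr & pbGate(pbValid) == 1L)
}
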