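POSTPROCESS_LEVELS <- c("none", "relaxation", "mm_min")

#' Solver portfolio
#'
#' An ordered list of solver configurations. Each solver is a base docking
#' pipeline paired with a post-processing tag (\code{none},
#' \code{relaxation} or \code{mm_min}); the same base pipeline with two
#' different tags counts as two distinct solvers. The order of the portfolio
#' is the tie-break priority used everywhere in the package: whenever two
#' solvers are exactly tied (argmax of scores, equal selection frequencies,
#' top-k set construction), the earlier index wins.
#'
#' @slot solverIds character; unique solver identifiers.
#' @slot baseNames character; base pipeline names.
#' @slot postprocess character; one of \code{none}, \code{relaxation},
#'   \code{mm_min} per solver.
#' @aliases Portfolio-class
#' @exportClass Portfolio
setClass("Portfolio",
  representation(solverIds = "character", baseNames = "character",
                 postprocess = "character"))

setValidity("Portfolio", function(object) {
  msg <- character()
  m <- length(object@solverIds)
  if (m < 2L) msg <- c(msg, "a portfolio needs at least 2 solvers")
  if (length(object@baseNames) != m || length(object@postprocess) != m)
    msg <- c(msg, "solverIds, baseNames, postprocess must have equal length")
  if (anyDuplicated(object@solverIds))
    msg <- c(msg, "solverIds must be unique")
  if (!all(object@postprocess %in% POSTPROCESS_LEVELS))
    msg <- c(msg, paste("postprocess must be one of:",
                        paste(POSTPROCESS_LEVELS, collapse = ", ")))
  if (anyDuplicated(paste(object@baseNames, object@postprocess)))
    msg <- c(msg, "(baseName, postprocess) pairs must be unique")
  if (length(msg)) msg else TRUE
})

#' @param baseNames character vector of base pipeline names.
#' @param postprocess post-processing tag(s), recycled to the base length.
#' @param solverIds optional explicit ids; by default the base name, with
#'   a \code{" (tag)"} suffix for non-\code{none} tags.
#' @return a \code{Portfolio}.
#' @examples
#' pf <- Portfolio(c("vina", "diffdock", "surfdock"))
#' nSolvers(pf)
#' @rdname Portfolio-class
#' @export
Portfolio <- function(baseNames, postprocess = "none", solverIds = NULL) {
  postprocess <- rep_len(as.character(postprocess), length(baseNames))
  if (is.null(solverIds))
    solverIds <- ifelse(postprocess == "none", baseNames,
                        sprintf("%s (%s)", baseNames, postprocess))
  new("Portfolio", solverIds = as.character(solverIds),
      baseNames = as.character(baseNames), postprocess = postprocess)
}

#' @rdname Portfolio-class
#' @export
setMethod("nSolvers", "Portfolio", function(x) length(x@solverIds))

#' @rdname Portfolio-class
#' @export
setMethod("solverIds", "Portfolio", function(x) x@solverIds)

setMethod("show", "Portfolio", function(object) {
  cat("Portfolio with", nSolvers(object), "solvers\n")
  df <- data.frame(solverId = object@solverIds, base = object@baseNames,
                   postprocess = object@postprocess)
  print(head(df, 10), row.names = FALSE)
  if (nSolvers(object) > 10) cat("...", nSolvers(object) - 10, "more\n")
})

#' Cross base solvers with post-processing variants
#'
#' Builds the "mixed" portfolio in which every base pipeline appears once
#' per requested post-processing variant, as distinct solvers. With 24 base
#' pipelines and variants \code{c("none", "relaxation")} this yields m = 48.
#' Base order is preserved and is the outer loop (all variants of base 1,
#' then base 2, ...), which fixes the tie-break priority.
#'
#' @param baseNames non-empty character vector of base pipeline names.
#' @param variants non-empty subset of \code{none}, \code{relaxation},
#'   \code{mm_min}.
#' @return a \code{Portfolio} with \code{length(baseNames) * length(variants)}
#'   solvers.
#' @export
buildMixedPortfolio <- function(baseNames, variants = c("none", "relaxation")) {
  if (length(baseNames) == 0L) stop("baseNames must be non-empty")
  if (length(variants) == 0L) stop("variants must be non-empty")
  if (!all(variants %in% POSTPROCESS_LEVELS))
    stop("unknown post-processing variant: ",
         paste(setdiff(variants, POSTPROCESS_LEVELS), collapse = ", "))
  base <- rep(baseNames, each = length(variants))
  post <- rep(variants, times = length(baseNames))
  Portfolio(base, post)
}
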