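#' Selector architecture configuration
#'
#' Hyperparameters of the embedding-based selector: an attentional pooler
#' compresses the residue-level protein embedding matrix into one protein
#' vector; that vector is concatenated with the ligand embedding and
#' linearly projected into a joint space; a stack of residual blocks
#' (linear -> batch norm -> ReLU -> linear, with a skip connection) refines
#' the joint vector; the concatenated block outputs feed a final linear
#' head emitting one logit per portfolio solver.
#'
#' Defaults follow the reference configuration: 1 attention head, joint
#' dimension 128, 4 residual blocks of width 256.
#'
#' @param dProtein residue embedding dimension (default 1152).
#' @param dLigand ligand embedding dimension (default 384).
#' @param nHeads attention heads; must divide \code{dProtein}.
#' @param jointDim fused representation dimension.
#' @param nBlocks number of residual blocks.
#' @param blockWidth hidden width inside each block.
#' @param mOut portfolio size (one output logit per solver).
#' @param seed integer; initialisation seed.
#' @return a validated list of class \code{"SelectorConfig"}.
#' @export
selectorConfig <- function(dProtein = 1152, dLigand = 384, nHeads = 1,
                           jointDim = 128, nBlocks = 4, blockWidth = 256,
                           mOut = 8, seed = 1L) {
  cfg <- list(dProtein = as.integer(dProtein), dLigand = as.integer(dLigand),
              nHeads = as.integer(nHeads), jointDim = as.integer(jointDim),
              nBlocks = as.integer(nBlocks),
              blockWidth = as.integer(blockWidth),
              mOut = as.integer(mOut), seed = as.integer(seed))
  if (any(unlist(cfg[1:7]) < 1L)) stop("all dimensions must be >= 1")
  if (cfg$dProtein %% cfg$nHeads != 0L)
    stop("dProtein must be divisible by nHeads")
  class(cfg) <- "SelectorConfig"
  cfg
}

#' Embedding-based docking algorithm selector
#'
#' Bundles a \code{\link{selectorConfig}}, the learned parameters and the
#' inference state (batch-norm running statistics). Create with
#' \code{\link{newSelector}}; run with \code{\link{predictSolvers}}.
#'
#' @slot config a \code{selectorConfig} list.
#' @slot params nested list of weight matrices/vectors.
#' @slot state list: batch-norm running means/vars, trained flag.
#' @aliases DockSelector-class
#' @exportClass DockSelector
setClass("DockSelector",
  representation(config = "list", params = "list", state = "list"))

fanInUniform <- function(nrow, ncol) {
  b <- 1 / sqrt(ncol)
  matrix(runif(nrow * ncol, -b, b), nrow, ncol)
}

#' Initialise a selector
#'
#' Linear maps use fan-in uniform initialisation, biases start at zero,
#' batch-norm scales at one; everything is drawn from the config seed so
#' identical configs yield bit-identical parameters.
#'
#' @param config a \code{\link{selectorConfig}}.
#' @return a \code{\link{DockSelector}}.
#' @export
newSelector <- function(config = selectorConfig()) {
  stopifnot(inherits(config, "SelectorConfig"))
  dH <- config$dProtein %/% config$nHeads
  params <- withLocalSeed(config$seed, {
    pooler <- lapply(seq_len(config$nHeads), function(h) list(
      q = runif(dH, -1 / sqrt(dH), 1 / sqrt(dH)),
      Wk = fanInUniform(dH, config$dProtein),
      Wv = fanInUniform(dH, config$dProtein)))
    fusion <- list(
      W = fanInUniform(config$jointDim, config$dProtein + config$dLigand),
      b = numeric(config$jointDim))
    blocks <- lapply(seq_len(config$nBlocks), function(k) list(
      W1 = fanInUniform(config$blockWidth, config$jointDim),
      b1 = numeric(config$blockWidth),
      gamma = rep(1, config$blockWidth),
      beta = numeric(config$blockWidth),
      W2 = fanInUniform(config$jointDim, config$blockWidth),
      b2 = numeric(config$jointDim)))
    head <- list(
      W = fanInUniform(config$mOut, config$nBlocks * config$jointDim),
      b = numeric(config$mOut))
    list(pooler = pooler, fusion = fusion, blocks = blocks, head = head)
  })
  state <- list(
    runMean = replicate(config$nBlocks, numeric(config$blockWidth),
                        simplify = FALSE),
    runVar = replicate(config$nBlocks, rep(1, config$blockWidth),
                       simplify = FALSE),
    bnMomentum = 0.1, bnEps = 1e-5, trained = FALSE, version = 1L)
  new("DockSelector", config = unclass(config), params = params,
      state = state)
}

#' @rdname DockSelector-class
#' @export
setMethod("nParams", "DockSelector", function(x)
  sum(rapply(x@params, length, how = "unlist")))

setMethod("show", "DockSelector", function(object) {
  cfg <- object@config
  cat("DockSelector (", if (isTRUE(object@state$trained)) "trained"
      else "untrained", ")\n", sep = "")
  cat("  pooler:", cfg$nHeads, "head(s) over", cfg$dProtein,
      "dim residue embeddings\n")
  cat("  fusion: [", cfg$dProtein, "+", cfg$dLigand, "] ->", cfg$jointDim,
      "\n")
  cat("  decoder:", cfg$nBlocks, "x ResBlock(", cfg$jointDim, ",",
      cfg$blockWidth, ") -> concat -> ", cfg$mOut, " logits\n")
  cat("  parameters:", format(nParams(object), big.mark = ","), "\n")
})

## ---- forward primitives -------------------------------------------------

## attention pooling over a stacked residue matrix; gi maps rows to
## instances (contiguous groups 1..B); returns pooled (B x dProtein) and,
## when cache = TRUE, everything backprop needs
poolForwardBatch <- function(params, config, proteinList, cache = FALSE) {
  lens <- vapply(proteinList, nrow, 1L)
  X <- do.call(rbind, proteinList)
  B <- length(proteinList)
  gi <- rep.int(seq_len(B), lens)
  dH <- config$dProtein %/% config$nHeads
  s <- sqrt(dH)
  pooled <- matrix(0, B, config$dProtein)
  hc <- vector("list", config$nHeads)
  for (h in seq_len(config$nHeads)) {
    ph <- params$pooler[[h]]
    K <- X %*% t(ph$Wk)
    e <- as.vector(K %*% ph$q) / s
    gmax <- vapply(split(e, gi), max, 0)
    ex <- exp(e - gmax[gi])
    gs <- rowsum(ex, gi)[, 1]
    alpha <- ex / gs[gi]
    V <- X %*% t(ph$Wv)
    pooled[, (h - 1L) * dH + seq_len(dH)] <- rowsum(V * alpha, gi)
    if (cache) hc[[h]] <- list(K = K, V = V, alpha = alpha)
  }
  if (cache) list(pooled = pooled, X = X, gi = gi, heads = hc, s = s)
  else list(pooled = pooled)
}

blockForward <- function(block, Z, rm, rv, eps, training, momentum) {
  H <- Z %*% t(block$W1) + rep(block$b1, each = nrow(Z))
  if (training) {
    mu <- colMeans(H)
    v <- colMeans(sweep(H, 2, mu)^2)
    rm <- (1 - momentum) * rm + momentum * mu
    rv <- (1 - momentum) * rv + momentum * v
  } else {
    mu <- rm; v <- rv
  }
  invstd <- 1 / sqrt(v + eps)
  Xhat <- sweep(sweep(H, 2, mu), 2, invstd, "*")
  Y <- sweep(sweep(Xhat, 2, block$gamma, "*"), 2, block$beta, "+")
  A <- pmax(Y, 0)
  Zout <- Z + A %*% t(block$W2) + rep(block$b2, each = nrow(Z))
  list(Zout = Zout, H = H, Xhat = Xhat, invstd = invstd, A = A, Zin = Z,
       runMean = rm, runVar = rv)
}

## full forward over a batch; L is the B x dLigand ligand matrix.
## mode zeroes one modality before fusion (modality-dropout ablation).
forwardBatch <- function(model, proteinList, L, training = FALSE,
                         mode = c("both", "protein_only", "ligand_only")) {
  mode <- match.arg(mode)
  cfg <- model@config
  pm <- model@params
  if (ncol(L) != cfg$dLigand)
    stop("ligand embedding dim ", ncol(L), " != configured ", cfg$dLigand)
  if (ncol(proteinList[[1]]) != cfg$dProtein)
    stop("protein embedding dim ", ncol(proteinList[[1]]),
         " != configured ", cfg$dProtein)
  pool <- poolForwardBatch(pm, cfg, proteinList, cache = training)
  pooled <- pool$pooled
  if (mode == "ligand_only") pooled <- pooled * 0
  Luse <- if (mode == "protein_only") L * 0 else L
  C <- cbind(pooled, Luse)
  Z <- C %*% t(pm$fusion$W) + rep(pm$fusion$b, each = nrow(C))
  blocks <- vector("list", cfg$nBlocks)
  st <- model@state
  for (k in seq_len(cfg$nBlocks)) {
    bf <- blockForward(pm$blocks[[k]], Z, st$runMean[[k]], st$runVar[[k]],
                       st$bnEps, training, st$bnMomentum)
    blocks[[k]] <- bf
    Z <- bf$Zout
  }
  Zcat <- do.call(cbind, lapply(blocks, `[[`, "Zout"))
  logits <- Zcat %*% t(pm$head$W) + rep(pm$head$b, each = nrow(Zcat))
  if (!all(is.finite(logits))) stop("non-finite logits in forward pass")
  list(logits = logits, pool = pool, C = C, blocks = blocks, Zcat = Zcat,
       mode = mode)
}

## analytic gradients of everything, given dLogits; mirrors params' shape
backwardBatch <- function(model, fw, dLogits) {
  cfg <- model@config
  pm <- model@params
  B <- nrow(dLogits)
  g <- list()
  g$head <- list(W = t(dLogits) %*% fw$Zcat, b = colSums(dLogits))
  dZcat <- dLogits %*% pm$head$W
  J <- cfg$jointDim
  dZ <- matrix(0, B, J)                # grad flowing into Z_k from above
  gBlocks <- vector("list", cfg$nBlocks)
  for (k in rev(seq_len(cfg$nBlocks))) {
    bf <- fw$blocks[[k]]
    blk <- pm$blocks[[k]]
    G <- dZ + dZcat[, (k - 1L) * J + seq_len(J), drop = FALSE]
    dA <- G %*% blk$W2
    gW2 <- t(G) %*% bf$A
    gb2 <- colSums(G)
    dY <- dA * (bf$A > 0)
    ggamma <- colSums(dY * bf$Xhat)
    gbeta <- colSums(dY)
    dXhat <- sweep(dY, 2, blk$gamma, "*")
    cs1 <- colSums(dXhat)
    cs2 <- colSums(dXhat * bf$Xhat)
    dH <- sweep(B * dXhat - rep(cs1, each = B) - bf$Xhat *
                  rep(cs2, each = B), 2, bf$invstd / B, "*")
    gW1 <- t(dH) %*% bf$Zin
    gb1 <- colSums(dH)
    gBlocks[[k]] <- list(W1 = gW1, b1 = gb1, gamma = ggamma, beta = gbeta,
                         W2 = gW2, b2 = gb2)
    dZ <- G + dH %*% blk$W1            # skip connection + linear path
  }
  g$blocks <- gBlocks
  g$fusion <- list(W = t(dZ) %*% fw$C, b = colSums(dZ))
  dC <- dZ %*% pm$fusion$W
  dPooled <- dC[, seq_len(cfg$dProtein), drop = FALSE]
  if (fw$mode == "ligand_only") dPooled <- dPooled * 0
  dH_ <- cfg$dProtein %/% cfg$nHeads
  pool <- fw$pool
  gPool <- vector("list", cfg$nHeads)
  for (h in seq_len(cfg$nHeads)) {
    ph <- pm$pooler[[h]]
    hc <- pool$heads[[h]]
    Gp <- dPooled[, (h - 1L) * dH_ + seq_len(dH_), drop = FALSE]
    Gpx <- Gp[pool$gi, , drop = FALSE]
    dV <- hc$alpha * Gpx
    gWv <- t(dV) %*% pool$X
    da <- rowSums(hc$V * Gpx)
    sg <- rowsum(hc$alpha * da, pool$gi)[, 1]
    de <- hc$alpha * (da - sg[pool$gi])
    gq <- as.vector(t(hc$K) %*% de) / pool$s
    gWk <- (ph$q %*% (t(de) %*% pool$X)) / pool$s
    gPool[[h]] <- list(q = gq, Wk = gWk, Wv = gWv)
  }
  g$pooler <- gPool
  g[c("pooler", "fusion", "blocks", "head")]
}

## ---- user-facing operations --------------------------------------------

#' Pool residue embeddings into one protein vector
#'
#' Per head: attention weights are a softmax over residues of the scaled
#' dot product between the head's learned query and the key projection of
#' each residue; the pooled head output is the attention-weighted sum of
#' value projections; heads concatenate back to the protein dimension.
#' There is no positional encoding, so the output is invariant to residue
#' order.
#'
#' @param model a \code{\link{DockSelector}}.
#' @param xP residue embedding matrix (nResidues x dProtein).
#' @return numeric vector of length dProtein.
#' @export
poolProtein <- function(model, xP) {
  if (ncol(xP) != model@config$dProtein)
    stop("residue matrix has ", ncol(xP), " columns, expected ",
         model@config$dProtein)
  as.vector(poolForwardBatch(model@params, model@config, list(xP))$pooled)
}

#' Fuse protein and ligand embeddings into the joint space
#'
#' Linear projection of the concatenation [pooled protein; ligand].
#'
#' @param model a \code{\link{DockSelector}}.
#' @param pooled protein vector (length dProtein).
#' @param xL ligand vector (length dLigand).
#' @return numeric vector of length jointDim.
#' @export
fuseEmbeddings <- function(model, pooled, xL) {
  cfg <- model@config
  if (length(pooled) != cfg$dProtein || length(xL) != cfg$dLigand)
    stop("embedding dimensions do not match the selector config")
  as.vector(model@params$fusion$W %*% c(pooled, xL) + model@params$fusion$b)
}

#' Decode a joint vector into per-solver logits
#'
#' Runs the residual-block stack in inference mode (batch norm uses running
#' statistics, so batch-size-1 decoding is well defined), concatenates all
#' block outputs and applies the linear head.
#'
#' @param model a \code{\link{DockSelector}}.
#' @param z joint vector (length jointDim).
#' @return numeric vector of mOut logits.
#' @export
decodeLogits <- function(model, z) {
  cfg <- model@config
  if (length(z) != cfg$jointDim) stop("z must have length jointDim")
  if (!all(is.finite(z))) stop("z must be finite")
  Z <- matrix(z, 1)
  st <- model@state
  outs <- vector("list", cfg$nBlocks)
  for (k in seq_len(cfg$nBlocks)) {
    bf <- blockForward(model@params$blocks[[k]], Z, st$runMean[[k]],
                       st$runVar[[k]], st$bnEps, FALSE, st$bnMomentum)
    outs[[k]] <- bf$Zout
    Z <- bf$Zout
  }
  Zcat <- do.call(cbind, outs)
  as.vector(Zcat %*% t(model@params$head$W) + model@params$head$b)
}

#' Predict solver scores and select a solver per instance
#'
#' Full inference pass: pool, fuse, decode, sigmoid. The selected solver is
#' the argmax of the logits with ties broken to the earliest portfolio
#' index; the margin is the difference between the top-1 and top-2
#' predicted probabilities (a confidence proxy).
#'
#' @param model a trained (or fresh) \code{\link{DockSelector}}.
#' @param instances an \code{\link{InstanceSet}}.
#' @param mode \code{"both"} (default) or the modality-dropout variants
#'   \code{"protein_only"} / \code{"ligand_only"} (the dropped modality is
#'   replaced by a zero vector before fusion).
#' @return list with \code{logits}, \code{probs} (n x m matrices),
#'   \code{selected} (integer solver indices) and \code{margin}.
#' @export
predictSolvers <- function(model, instances,
                           mode = c("both", "protein_only", "ligand_only")) {
  mode <- match.arg(mode)
  fw <- forwardBatch(model, proteinEmbeddings(instances),
                     ligandEmbeddings(instances), training = FALSE,
                     mode = mode)
  probs <- sigmoid(fw$logits)
  selected <- apply(fw$logits, 1, argmaxFirst)
  margin <- apply(probs, 1, function(p) {
    sp <- sort(p, decreasing = TRUE)
    sp[1] - sp[2]
  })
  rownames(fw$logits) <- rownames(probs) <- instanceIds(instances)
  list(logits = fw$logits, probs = probs, selected = as.integer(selected),
       margin = as.numeric(margin))
}

## ---- checkpointing ------------------------------------------------------

#' Save / load a selector checkpoint
#'
#' A single archive holding the parameters and inference state, with the
#' configuration embedded as JSON metadata and a mandatory version field.
#'
#' @param model a \code{\link{DockSelector}}.
#' @param path checkpoint path.
#' @return \code{path} / a \code{DockSelector}.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(format = "dockselect-checkpoint", version = 1L,
               configJSON = jsonlite::toJSON(model@config, auto_unbox = TRUE),
               params = model@params, state = model@state), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "dockselect-checkpoint") || is.null(obj$version))
    stop(path, " is not a selector checkpoint")
  cfg <- jsonlite::fromJSON(obj$configJSON)
  new("DockSelector", config = lapply(cfg, function(x)
        if (is.numeric(x)) as.integer(x) else x),
      params = obj$params, state = obj$state)
}
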