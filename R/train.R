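## elementwise recursion over parameter trees (nested lists of numerics)
paramMap2 <- function(a, b, f) {
  if (is.list(a)) return(mapply(paramMap2, a, b, MoreArgs = list(f = f),
                                SIMPLIFY = FALSE))
  f(a, b)
}

paramZeroLike <- function(a) {
  if (is.list(a)) return(lapply(a, paramZeroLike))
  a * 0
}

#' Training configuration
#'
#' Adam with a cosine learning-rate schedule spanning \code{maxEpochs}
#' (no restarts) and early stopping on the held-out fold's relaxed-criterion
#' selection success rate, restoring the best-epoch parameters. The loss is
#' a non-negative weighted mix of binary cross-entropy with logits
#' (primary), MSE, pairwise logistic and smooth NDCG at 3.
#'
#' @param lr base learning rate.
#' @param batchSize mini-batch size.
#' @param maxEpochs maximum epochs (cosine schedule horizon).
#' @param patience epochs without validation improvement before stopping.
#' @param lossMix named non-negative weights \code{bce}, \code{mse},
#'   \code{pairwise}, \code{ndcg3}; at least one positive.
#' @param tieTol pairwise-loss tie tolerance on the target scale.
#' @param ndcgTemp NDCG surrogate temperature.
#' @param seed integer seed for batching order.
#' @return a validated list of class \code{"TrainConfig"}.
#' @export
trainConfig <- function(lr = 1e-3, batchSize = 64L, maxEpochs = 200L,
                        patience = 20L,
                        lossMix = c(bce = 1, mse = 0, pairwise = 0,
                                    ndcg3 = 0),
                        tieTol = 1e-6, ndcgTemp = 1, seed = 1L) {
  mix <- c(bce = 0, mse = 0, pairwise = 0, ndcg3 = 0)
  mix[names(lossMix)] <- lossMix
  if (any(mix < 0) || all(mix == 0))
    stop("lossMix weights must be >= 0 with at least one positive")
  if (patience >= maxEpochs) stop("patience must be < maxEpochs")
  cfg <- list(lr = lr, batchSize = as.integer(batchSize),
              maxEpochs = as.integer(maxEpochs),
              patience = as.integer(patience), lossMix = mix,
              tieTol = tieTol, ndcgTemp = ndcgTemp, seed = as.integer(seed))
  class(cfg) <- "TrainConfig"
  cfg
}

adamUpdate <- function(params, grads, mS, vS, lr, t, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  mS <- paramMap2(mS, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  vS <- paramMap2(vS, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  step <- paramMap2(mS, vS, function(m, v)
    lr * (m / c1) / (sqrt(v / c2) + eps))
  params <- paramMap2(params, step, `-`)
  list(params = params, mS = mS, vS = vS)
}

#' Train a selector on a performance table
#'
#' Minimises the configured loss mix on the gated composite-score targets
#' of the training folds; the held-out fold supplies the early-stopping
#' validation metric (top-1 selection success rate under the relaxed
#' criterion). Fully seeded: identical inputs, configs and seeds give
#' identical loss trajectories and final parameters.
#'
#' @param table a \code{\link{PerformanceTable}}.
#' @param instances an \code{\link{InstanceSet}} covering the table rows.
#' @param folds fold assignment from \code{\link{makeKFold}}.
#' @param fold index of the held-out fold.
#' @param selConfig a \code{\link{selectorConfig}}; \code{mOut} and the
#'   embedding dims are overridden from the data.
#' @param tConfig a \code{\link{trainConfig}}.
#' @param mode modality mode (see \code{\link{predictSolvers}}).
#' @param verbose print per-epoch progress.
#' @return list with \code{model} (trained \code{DockSelector}),
#'   \code{report} (epoch losses, validation metric, best epoch) and
#'   \code{valIds} (held-out instance ids).
#' @export
trainSelector <- function(table, instances, folds, fold = 0L,
                          selConfig = selectorConfig(),
                          tConfig = trainConfig(),
                          mode = c("both", "protein_only", "ligand_only"),
                          verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(tConfig, "TrainConfig"))
  ids <- instanceIds(table)
  if (!all(ids %in% instanceIds(instances)))
    stop("instances must cover every table row")
  if (!fold %in% folds) stop("fold ", fold, " not present in the split")
  trainIds <- ids[folds[ids] != fold]
  valIds <- ids[folds[ids] == fold]
  if (length(trainIds) < tConfig$batchSize)
    stop("fewer training instances than one batch")
  dims <- embeddingDims(instances)
  cfg <- selectorConfig(dProtein = dims["dProtein"],
                        dLigand = dims["dLigand"],
                        nHeads = selConfig$nHeads,
                        jointDim = selConfig$jointDim,
                        nBlocks = selConfig$nBlocks,
                        blockWidth = selConfig$blockWidth,
                        mOut = ncol(table), seed = selConfig$seed)
  model <- newSelector(cfg)
  targets <- scores(table)
  succRel <- successMatrix(table, "relaxed")
  trainSet <- subsetInstances(instances, trainIds)
  valSet <- subsetInstances(instances, valIds)
  protTrain <- proteinEmbeddings(trainSet)
  ligTrain <- ligandEmbeddings(trainSet)
  tgtTrain <- targets[trainIds, , drop = FALSE]

  mS <- paramZeroLike(model@params)
  vS <- paramZeroLike(model@params)
  nTrain <- length(trainIds)
  epochLoss <- valMetric <- numeric(0)
  best <- list(metric = -Inf, epoch = 0L, params = model@params,
               state = model@state)
  stepT <- 0L
  orders <- withLocalSeed(tConfig$seed,
    lapply(seq_len(tConfig$maxEpochs), function(e) sample.int(nTrain)))

  for (epoch in seq_len(tConfig$maxEpochs)) {
    lr <- tConfig$lr * 0.5 * (1 + cos(pi * (epoch - 1) / tConfig$maxEpochs))
    ord <- orders[[epoch]]
    starts <- seq(1, nTrain, by = tConfig$batchSize)
    losses <- numeric(0)
    for (s in starts) {
      idx <- ord[s:min(s + tConfig$batchSize - 1L, nTrain)]
      if (length(idx) < 2L) next       # batch norm needs >= 2 samples
      fw <- forwardBatch(model, protTrain[idx],
                         ligTrain[idx, , drop = FALSE], training = TRUE,
                         mode = mode)
      lg <- batchLossAndGrad(fw$logits, tgtTrain[idx, , drop = FALSE],
                             tConfig$lossMix, tConfig$tieTol,
                             tConfig$ndcgTemp)
      if (!is.finite(lg$loss))
        stop("non-finite training loss at epoch ", epoch)
      grads <- backwardBatch(model, fw, lg$grad)
      stepT <- stepT + 1L
      upd <- adamUpdate(model@params, grads, mS, vS, lr, stepT)
      model@params <- upd$params
      mS <- upd$mS
      vS <- upd$vS
      ## commit batch-norm running statistics from this batch
      for (k in seq_len(cfg$nBlocks)) {
        model@state$runMean[[k]] <- fw$blocks[[k]]$runMean
        model@state$runVar[[k]] <- fw$blocks[[k]]$runVar
      }
      losses <- c(losses, lg$loss)
    }
    epochLoss[epoch] <- mean(losses)
    pred <- predictSolvers(model, valSet, mode = mode)
    valMetric[epoch] <- mean(succRel[valIds, , drop = FALSE][
      cbind(seq_along(valIds), pred$selected)])
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val %.4f", epoch,
                      epochLoss[epoch], valMetric[epoch]))
    if (valMetric[epoch] > best$metric) {
      best <- list(metric = valMetric[epoch], epoch = epoch,
                   params = model@params, state = model@state)
    } else if (epoch - best$epoch >= tConfig$patience) {
      break
    }
  }
  model@params <- best$params
  model@state <- best$state
  model@state$trained <- TRUE
  list(model = model,
       report = list(epochLoss = epochLoss, valMetric = valMetric,
                     bestEpoch = best$epoch, bestValMetric = best$metric,
                     nEpochs = length(epochLoss),
                     seed = tConfig$seed, lossMix = tConfig$lossMix),
       valIds = valIds)
}

#' Run the full k-fold training/evaluation protocol
#'
#' Trains one selector per fold and collects the held-out predictions so
#' that every instance is evaluated exactly once by a model that never saw
#' it. Returns per-fold models plus the stitched out-of-fold selections.
#'
#' @inheritParams trainSelector
#' @param k number of folds.
#' @param foldSeed seed for the fold split.
#' @return list with \code{models}, \code{reports}, \code{selections}
#'   (named integer vector over all instances), \code{predictions}
#'   (list of per-fold prediction objects) and \code{folds}.
#' @export
crossValidateSelector <- function(table, instances, k = 5L, foldSeed = 1L,
                                  selConfig = selectorConfig(),
                                  tConfig = trainConfig(),
                                  mode = "both", verbose = FALSE) {
  ids <- instanceIds(table)
  folds <- makeKFold(ids, k = k, seed = foldSeed)
  selections <- setNames(integer(length(ids)), ids)
  margins <- setNames(numeric(length(ids)), ids)
  models <- reports <- preds <- vector("list", k)
  for (f in seq_len(k) - 1L) {
    fit <- trainSelector(table, instances, folds, fold = f,
                         selConfig = selConfig, tConfig = tConfig,
                         mode = mode, verbose = verbose)
    pred <- predictSolvers(fit$model, subsetInstances(instances, fit$valIds),
                           mode = mode)
    selections[fit$valIds] <- pred$selected
    margins[fit$valIds] <- pred$margin
    models[[f + 1L]] <- fit$model
    reports[[f + 1L]] <- fit$report
    preds[[f + 1L]] <- c(pred, list(ids = fit$valIds))
  }
  list(models = models, reports = reports, selections = selections,
       margins = margins, predictions = preds, folds = folds)
}
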