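test_that("attention pooling degenerates correctly for a single residue", {
  model <- tinyModel()
  x <- matrix(rnorm(8), 1, 8)
  pooled <- poolProtein(model, x)
  ## softmax over one residue is 1: pooled = concatenated value projections
  expected <- c(as.vector(model@params$pooler[[1]]$Wv %*% x[1, ]),
                as.vector(model@params$pooler[[2]]$Wv %*% x[1, ]))
  expect_equal(pooled, expected, tolerance = 1e-12)
})

test_that("pooling renormalises over duplicated residues", {
  model <- tinyModel()
  x <- matrix(rnorm(8), 1, 8)
  x3 <- x[c(1, 1, 1), , drop = FALSE]
  expect_equal(poolProtein(model, x3), poolProtein(model, x),
               tolerance = 1e-12)
})

test_that("pooling is invariant to residue order for 1, 2 and 4 heads", {
  for (heads in c(1, 2, 4)) {
    model <- newSelector(selectorConfig(dProtein = 8, dLigand = 4,
                                        nHeads = heads, jointDim = 5,
                                        nBlocks = 2, blockWidth = 7,
                                        mOut = 3, seed = heads))
    set.seed(heads + 10)
    for (rep in 1:5) {
      x <- matrix(rnorm(7 * 8), 7, 8)
      perm <- sample(7)
      expect_equal(poolProtein(model, x[perm, ]), poolProtein(model, x),
                   tolerance = 1e-6)
    }
  }
  expect_error(poolProtein(tinyModel(), matrix(0, 2, 5)), "columns")
})

test_that("fusion is the linear map of the concatenated embeddings", {
  model <- zeroParams(tinyModel())
  expect_identical(fuseEmbeddings(model, rnorm(8), rnorm(4)), rep(0, 5))
  ## identity-like projection picks out one coordinate of [pooled; ligand]
  model@params$fusion$W[3, 10] <- 1    # coordinate 2 of the ligand part
  xL <- c(0, 7.5, 0, 0)
  expect_identical(fuseEmbeddings(model, rep(0, 8), xL),
                   c(0, 0, 7.5, 0, 0))
  expect_identical(length(fuseEmbeddings(tinyModel(), rnorm(8), rnorm(4))),
                   5L)
  expect_error(fuseEmbeddings(tinyModel(), rnorm(3), rnorm(4)), "dimensions")
})

test_that("decoder blocks reduce to identity when W2 = 0", {
  model <- zeroParams(tinyModel())
  ## with W1 = W2 = 0 each block passes z through; head then reads the
  ## concatenated copies
  model@params$head$W[1, 1] <- 1       # z1 from block 1's output
  model@params$head$W[2, 6] <- 1       # z1 from block 2's output
  model@params$head$W[3, 2] <- 1       # z2 from block 1's output
  z <- c(1.5, -2, 0, 3, 4)
  expect_equal(decodeLogits(model, z), c(1.5, 1.5, -2), tolerance = 1e-12)
  expect_error(decodeLogits(model, c(1, Inf, 0, 0, 0)), "finite")
})

test_that("zeroed parameters give zero logits, 0.5 probs and tie-break", {
  model <- zeroParams(tinyModel())
  inst <- randomInstances(4, seed = 3)
  pred <- predictSolvers(model, inst)
  expect_true(all(pred$logits == 0))
  expect_true(all(pred$probs == 0.5))
  expect_true(all(pred$selected == 1L))  # earliest index wins ties
  expect_true(all(pred$margin == 0))
})

test_that("selection follows the logits through the sigmoid", {
  model <- zeroParams(tinyModel())
  model@params$head$b <- c(2, -1, 0)
  pred <- predictSolvers(model, randomInstances(3, seed = 5))
  expect_true(all(pred$selected == 1L))
  expect_equal(pred$probs[1, ], 1 / (1 + exp(-c(2, -1, 0))),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(pred$margin[1],
               1 / (1 + exp(-2)) - 1 / (1 + exp(0)), tolerance = 1e-12)
  ## two tied maxima resolve to the earlier portfolio index
  model4 <- zeroParams(tinyModel(mOut = 4))
  model4@params$head$b <- c(-1, 5, 0, 5)
  pred4 <- predictSolvers(model4, randomInstances(3, seed = 5))
  expect_true(all(pred4$selected == 2L))
})

test_that("modality dropout makes the output blind to the dropped input", {
  model <- tinyModel()
  inst <- randomInstances(4, seed = 8)
  instL <- InstanceSet(instanceIds(inst), proteinEmbeddings(inst),
                       ligandEmbeddings(inst) + 10)
  instP <- InstanceSet(instanceIds(inst),
                       lapply(proteinEmbeddings(inst), function(m) m + 10),
                       ligandEmbeddings(inst))
  expect_identical(predictSolvers(model, inst, "both")$logits,
                   predictSolvers(model, inst)$logits)
  expect_identical(predictSolvers(model, inst, "protein_only")$logits,
                   predictSolvers(model, instL, "protein_only")$logits)
  expect_identical(predictSolvers(model, inst, "ligand_only")$logits,
                   predictSolvers(model, instP, "ligand_only")$logits)
  expect_false(identical(predictSolvers(model, inst)$logits,
                         predictSolvers(model, instL)$logits))
  expect_error(predictSolvers(model, inst, "neither"))
})

test_that("initialisation and inference are seed-deterministic", {
  a <- tinyModel(seed = 99)
  b <- tinyModel(seed = 99)
  expect_identical(a@params, b@params)
  inst <- randomInstances(3, seed = 1)
  expect_identical(predictSolvers(a, inst), predictSolvers(b, inst))
  expect_false(identical(tinyModel(seed = 100)@params, a@params))
})

test_that("parameter count is a pure function of the configuration", {
  expect_identical(nParams(tinyModel(seed = 1)), nParams(tinyModel(seed = 2)))
  ## default configuration lands at the expected order of magnitude
  n <- nParams(newSelector(selectorConfig()))
  expect_gt(n, 1e5)
  expect_lt(n, 1e7)
  expect_gt(nParams(tinyModel(mOut = 5)), nParams(tinyModel(mOut = 3)))
})

test_that("checkpoints round-trip the model exactly", {
  model <- tinyModel(seed = 13)
  path <- tempfile(fileext = ".rds")
  saveCheckpoint(model, path)
  model2 <- loadCheckpoint(path)
  inst <- randomInstances(3, seed = 2)
  expect_identical(predictSolvers(model2, inst), predictSolvers(model, inst))
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(loadCheckpoint(bad), "checkpoint")
})
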