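test_that("generation is bit-reproducible from the spec seed", {
  spec <- syntheticSpec(nInstances = 40, mSolvers = 4, nRegimes = 2,
                        dProtein = 16, dLigand = 8, seed = 9)
  a <- generateBenchmark(spec)
  b <- generateBenchmark(spec)
  expect_identical(scores(a$table), scores(b$table))
  expect_identical(proteinEmbeddings(a$instances),
                   proteinEmbeddings(b$instances))
  expect_identical(a$regimes, b$regimes)
  c <- generateBenchmark(syntheticSpec(nInstances = 40, mSolvers = 4,
                                       nRegimes = 2, dProtein = 16,
                                       dLigand = 8, seed = 10))
  expect_false(identical(scores(a$table), scores(c$table)))
})

test_that("planted dominant solvers win the oracle on most instances", {
  spec <- syntheticSpec(nInstances = 600, mSolvers = 6, nRegimes = 3,
                        separability = 6, seed = 0)
  bench <- generateBenchmark(spec)
  dominant <- ((bench$regimes - 1) %% 6) + 1
  winner <- apply(scores(bench$table), 1, which.max)
  expect_gte(mean(winner == dominant), 0.9)
})

test_that("without regime structure the oracle is nearly degenerate", {
  ## one globally dominant solver, identical skill in every regime
  sk <- matrix(4, 3, 6)
  sk[, 1] <- 0.5
  spec <- syntheticSpec(nInstances = 2000, mSolvers = 6, nRegimes = 3,
                        separability = 0, skill = sk, seed = 1)
  bench <- generateBenchmark(spec)
  sbs <- singleBestSolver(bench$table, "relaxed")$performance
  vbs <- vbsCurve(bench$table, "relaxed")$mean
  expect_lt(100 * (vbs - sbs), 3)      # gap below 3 percentage points
})

test_that("per-cell success rates match truncated-normal x Bernoulli", {
  sk <- rbind(c(1.2, 2.8), c(0.6, 3.5))
  pb <- rbind(c(0.9, 0.7), c(0.95, 0.6))
  spec <- syntheticSpec(nInstances = 10000, mSolvers = 2, nRegimes = 2,
                        separability = 0, skill = sk, pbPassProb = pb,
                        rmsdNoiseSd = 1, dProtein = 8, dLigand = 4,
                        proteinLenRange = c(2L, 4L), seed = 4)
  bench <- generateBenchmark(spec)
  succ <- successMatrix(bench$table, "relaxed")
  ## analytic oracle: P(truncN(mu, 1) <= 2) * pbPass, per regime and solver
  truncP <- function(thr, mu, sd) {
    (pnorm((thr - mu) / sd) - pnorm(-mu / sd)) / (1 - pnorm(-mu / sd))
  }
  for (r in 1:2) for (a in 1:2) {
    idx <- bench$regimes == r
    expected <- truncP(2, sk[r, a], 1) * pb[r, a]
    expect_lt(abs(mean(succ[idx, a]) - expected), 0.02)
  }
})

test_that("log-normal RMSD generation is supported and positive", {
  spec <- syntheticSpec(nInstances = 100, mSolvers = 3, nRegimes = 2,
                        dProtein = 8, dLigand = 4, rmsdDist = "lognormal",
                        skill = matrix(c(1, 2, 3, 3, 2, 1), 2, 3), seed = 2)
  bench <- generateBenchmark(spec)
  r <- SummarizedExperiment::assay(bench$table, "rmsd")
  expect_true(all(r > 0))
  expect_error(syntheticSpec(skill = matrix(0, 3, 6),
                             rmsdDist = "lognormal"), "positive")
})

test_that("zero perturbation is the identity; targeted shifts move the SBS", {
  spec <- syntheticSpec(nInstances = 300, mSolvers = 4, nRegimes = 2,
                        dProtein = 8, dLigand = 4, seed = 6,
                        skill = rbind(c(1.0, 1.3, 3, 4), c(1.0, 1.3, 3, 4)))
  bench <- generateBenchmark(spec)
  same <- perturbProtocol(bench, rmsdShift = 0, pbFlipProb = 0)
  expect_identical(scores(same$table), scores(bench$table))
  sbs0 <- singleBestSolver(bench$table, "mean_score")$index
  shift <- rep(0, 4); shift[sbs0] <- 2.5
  moved <- perturbProtocol(bench, rmsdShift = shift)
  expect_false(singleBestSolver(moved$table, "mean_score")$index == sbs0)
  ## RMSDs stay floored at zero
  neg <- perturbProtocol(bench, rmsdShift = -10)
  expect_true(all(SummarizedExperiment::assay(neg$table, "rmsd") >= 0))
})

test_that("fixtures round-trip through CSV + store + manifest", {
  spec <- syntheticSpec(nInstances = 25, mSolvers = 3, nRegimes = 2,
                        dProtein = 8, dLigand = 4, seed = 3)
  bench <- generateBenchmark(spec)
  dir <- file.path(tempdir(), "fixture-rt")
  manifest <- writeFixture(bench, dir)
  man <- yaml::read_yaml(manifest)
  expect_identical(man$regime, "separated")
  loaded <- loadBenchmark(manifest)
  expect_identical(scores(loaded$table), scores(bench$table))
  expect_identical(solverIds(portfolio(loaded$table)),
                   solverIds(portfolio(bench$table)))
  expect_equal(proteinEmbeddings(loaded$instances),
               proteinEmbeddings(bench$instances))
  ## the empty blocklist applies no removals
  expect_identical(nrow(loaded$table), 25L)
})

test_that("spec validation rejects inconsistent inputs", {
  expect_error(syntheticSpec(skill = matrix(1, 2, 2)), "nRegimes x mSolvers")
  expect_error(syntheticSpec(pbPassProb = 1.5), "\\[0, 1\\]")
  expect_error(syntheticSpec(separability = -1), ">= 0")
  expect_error(syntheticSpec(nRegimes = 40, dProtein = 8, dLigand = 4,
                             skill = matrix(1, 40, 6)), "nRegimes <=")
})
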