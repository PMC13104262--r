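## table whose relaxed success matrix is exactly [[1,0],[1,0],[0,1]]
threeByTwo <- function() {
  rmsd <- rbind(c(0.5, 5), c(0.5, 5), c(5, 0.5))
  rownames(rmsd) <- c("i1", "i2", "i3")
  makeTable(rmsd)
}

test_that("SBS is the argmax of column means with earliest-index ties", {
  pt <- threeByTwo()
  sbs <- singleBestSolver(pt, "relaxed")
  expect_identical(sbs$index, 1L)
  expect_equal(sbs$performance, 2 / 3, tolerance = 1e-12)
  ## all-equal columns: tie resolves to solver 1
  ptEq <- makeTable(rbind(c(1, 1), c(3, 3)))
  expect_identical(singleBestSolver(ptEq, "relaxed")$index, 1L)
  ## single instance: argmax of the row
  pt1 <- makeTable(rbind(c(5, 0.5)))
  expect_identical(singleBestSolver(pt1, "relaxed")$index, 2L)
})

test_that("VBS is the row maximum and dominates every column mean", {
  pt <- threeByTwo()
  v <- vbsCurve(pt, "relaxed")
  expect_identical(unname(v$perInstance), c(1L, 1L, 1L))
  expect_identical(v$mean, 1)
  M <- successMatrix(pt, "relaxed")
  expect_true(all(v$mean >= colMeans(M)))
  ptC <- makeTable(rbind(c(1.5, 1.5), c(1.5, 1.5)))
  expect_equal(vbsCurve(ptC, "mean_score")$mean, rmsdScore(1.5),
               tolerance = 1e-12)
})

test_that("VBS@K walks down the per-instance order statistics", {
  sc <- c(0.9, 0.7, 0.2)
  ## invert the score function to plant exact composite scores in the table
  lam <- 3
  inv <- function(s) 2 + log((1 + exp(-2 * lam)) / s - 1) / lam
  pt <- makeTable(matrix(inv(sc), 1, 3))
  expect_equal(vbsAtK(pt, 2, "mean_score")$mean, 0.7, tolerance = 1e-9)
  expect_equal(vbsAtK(pt, 1, "mean_score")$mean,
               vbsCurve(pt, "mean_score")$mean, tolerance = 1e-12)
  expect_equal(vbsAtK(pt, 3, "mean_score")$mean, 0.2, tolerance = 1e-9)
  expect_error(vbsAtK(pt, 4), "1..3")
  expect_error(vbsAtK(pt, 0), "1..3")
})

test_that("Selected@K ranks solvers by selection frequency", {
  sel <- c(1, 1, 2, 1, 3, 2)            # A,A,B,A,C,B
  expect_identical(selectedAtK(sel, 1)$index, 1L)
  expect_identical(selectedAtK(sel, 1)$count, 3L)
  expect_identical(selectedAtK(sel, 2)$index, 2L)
  expect_identical(selectedAtK(sel, 3)$index, 3L)
  expect_error(selectedAtK(sel, 4), "distinct")
  allSame <- rep(2L, 10)
  expect_identical(selectedAtK(allSame, 1, m = 4)$count, 10L)
  tied <- c(1, 1, 2, 2)
  expect_identical(selectedAtK(tied, 1)$index, 1L)
})

test_that("gap closure interpolates between SBS (0) and VBS (100)", {
  expect_equal(gapClosed(2 / 3, 2 / 3, 1), 0)
  expect_equal(gapClosed(1, 2 / 3, 1), 100)
  expect_equal(gapClosed(0.8, 2 / 3, 1), 40, tolerance = 1e-9)
  expect_warning(g <- gapClosed(0.5, 0.7, 0.7), "undefined")
  expect_true(is.na(g))
  expect_error(gapClosed(0.5, 0.9, 0.7), "oracle")
  expect_lt(gapClosed(0.6, 2 / 3, 1), 0)   # gap widening is representable
})

test_that("improvement is the difference on the percent scale", {
  expect_equal(improvement(50.01, 43.41), 6.60, tolerance = 1e-9)
  expect_equal(improvement(74.68, 68.17), 6.51, tolerance = 1e-9)
  expect_identical(improvement(40, 40), 0)
})

test_that("rank stability reproduces the hand-enumerated reversal case", {
  ## mean-score order (s1 > s2 > s3) versus its exact reversal
  p <- makeTable(rbind(c(0.5, 1.0, 1.5), c(0.7, 1.2, 1.7)))
  q <- makeTable(rbind(c(1.5, 1.0, 0.5), c(1.7, 1.2, 0.7)))
  st <- rankStability(p, q)
  expect_equal(st$spearman, -1, tolerance = 1e-12)
  expect_equal(st$kendallTauB, -1, tolerance = 1e-12)
  expect_identical(st$j1, 0)
  expect_equal(st$jkCurve, c(0, 1 / 3, 1), tolerance = 1e-12)
  expect_equal(st$jbar, 4 / 9, tolerance = 1e-12)
  ## identity gives perfect agreement everywhere
  stId <- rankStability(p, p)
  expect_equal(stId$spearman, 1)
  expect_equal(stId$kendallTauB, 1)
  expect_true(all(stId$jkCurve == 1))
  pf2 <- makeTable(rbind(c(1, 2), c(2, 1)))
  expect_error(rankStability(p, pf2), "identical portfolio")
})

test_that("tau-b and Spearman match reference implementations on ties", {
  set.seed(77)
  for (rep in 1:60) {
    m <- sample(3:8, 1)
    x <- sample(1:4, m, replace = TRUE) + runif(m) * (rep %% 2)
    y <- sample(1:4, m, replace = TRUE) + runif(m) * (rep %% 3 == 0)
    expect_equal(DockSelect:::kendallTauB(x, y), naiveTauB(x, y),
                 tolerance = 1e-12)
    if (sd(x) > 0 && sd(y) > 0)
      expect_equal(DockSelect:::kendallTauB(x, y),
                   cor(x, y, method = "kendall"), tolerance = 1e-9)
  }
})

test_that("oracle entropy spans 0 to log2(m) with fractional tie mass", {
  ## one solver dominates everywhere: no selection headroom
  dom <- makeTable(matrix(rep(c(0.5, 4, 4, 4), each = 5), 5, 4))
  expect_identical(vbsEntropy(dom), 0)
  ## winners uniform over 8 solvers
  rmsd <- matrix(4, 8, 8)
  diag(rmsd) <- 0.5
  expect_equal(vbsEntropy(makeTable(rmsd)), 3, tolerance = 1e-12)
  ## win counts (2, 1, 1) over 4 instances -> 1.5 bits
  r4 <- rbind(c(0.5, 4, 4, 4), c(0.5, 4, 4, 4),
              c(4, 0.5, 4, 4), c(4, 4, 0.5, 4))
  expect_equal(vbsEntropy(makeTable(r4)), 1.5, tolerance = 1e-12)
  ## bounded by [0, log2 m] on random tables
  for (s in 1:20) {
    pt <- randomTable(12, 5, seed = 200 + s)
    h <- vbsEntropy(pt)
    expect_gte(h, 0)
    expect_lte(h, log2(5) + 1e-12)
  }
})

test_that("margin reliability uses equal-mass bins and self-consistency", {
  set.seed(55)
  pt <- randomTable(1200, 4, seed = 91, tieProb = 0)
  oracleSel <- apply(scores(pt), 1, which.max)
  margins <- runif(1200)
  mr <- marginReliability(oracleSel, margins, pt, nBins = 12)
  expect_true(all(mr$n == 100))
  expect_true(all(mr$reliability == 1))
  sbsIdx <- singleBestSolver(pt, "mean_score")$index
  mrS <- marginReliability(rep(sbsIdx, 1200), margins, pt, nBins = 12)
  expect_true(all(mrS$pBeatSbs == 0))
  expect_true(all(mrS$pAtLeastSbs == 1))
  ## remainder instances land in the lowest-margin bins
  pt2 <- randomTable(125, 3, seed = 17, tieProb = 0)
  mr2 <- marginReliability(rep(1L, 125), runif(125), pt2, nBins = 12)
  expect_identical(mr2$n, c(rep(11L, 5), rep(10L, 7)))
  expect_error(marginReliability(rep(1L, 5), runif(5), randomTable(5, 3, 1),
                                 nBins = 12), "nBins")
})

test_that("selection distributions aggregate selector and oracle mass", {
  pt <- makeTable(matrix(rep(c(0.5, 4, 4), each = 6), 6, 3))
  sd1 <- selectionDistribution(rep(1L, 6), pt, top = 1)
  expect_identical(sd1$perSolver$selectorFreq, 1)
  expect_identical(sd1$perSolver$oracleFreq, 1)
  expect_identical(sd1$agreementRate, 1)
  set.seed(6)
  pt2 <- randomTable(50, 4, seed = 31, tieProb = 0)
  sel <- sample(1:4, 50, replace = TRUE)
  sd2 <- selectionDistribution(sel, pt2)
  expect_equal(sum(sd2$selectorFreqAll), 1, tolerance = 1e-12)
})

test_that("evaluation report recovers the oracle and SBS endpoints", {
  pt <- randomTable(40, 5, seed = 12, tieProb = 0)
  oracleSel <- apply(scores(pt), 1, which.max)
  repO <- evaluateSelections(oracleSel, pt)
  expect_equal(repO$relaxed$gapClosedPercent, 100, tolerance = 1e-9)
  expect_equal(repO$strict$gapClosedPercent, 100, tolerance = 1e-9)
  sbsIdx <- singleBestSolver(pt, "relaxed")$index
  repS <- evaluateSelections(rep(sbsIdx, 40), pt)
  expect_equal(repS$relaxed$gapClosedPercent, 0, tolerance = 1e-9)
  expect_identical(repS$relaxed$pValue, 1.0)
  expect_output(print(repO), "gap closed")
})
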