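#' Specification for a synthetic docking benchmark
#'
#' Emulates the statistical structure of a docking algorithm-selection
#' benchmark without any real docking runs: instances fall into latent
#' regimes; residue and ligand embeddings are drawn around regime
#' centroids placed \code{separability} noise-SDs apart (unit isotropic
#' noise); per-solver RMSDs follow a zero-truncated normal (or log-normal)
#' around the regime-by-solver skill means; PoseBusters flags are
#' Bernoulli. Composite scores and success labels are then derived through
#' the scoring module exactly as for real data.
#'
#' @param nInstances number of complexes.
#' @param mSolvers portfolio size.
#' @param nRegimes number of latent solver regimes.
#' @param separability centroid spacing delta, in units of the unit noise
#'   SD; 0 means embeddings carry no regime signal.
#' @param skill nRegimes x mSolvers matrix of mean RMSD (Angstrom).
#' @param rmsdNoiseSd RMSD noise SD (Angstrom).
#' @param pbPassProb scalar or nRegimes x mSolvers matrix of PB pass
#'   probabilities.
#' @param proteinLenRange integer (min, max) residues per protein.
#' @param dProtein,dLigand embedding dimensions (small defaults keep tests
#'   fast; the full 1152/384 are available).
#' @param rmsdDist \code{"truncnorm"} (default) or \code{"lognormal"}.
#' @param seed integer master seed.
#' @return a validated list of class \code{"SyntheticSpec"}.
#' @export
syntheticSpec <- function(nInstances = 600L, mSolvers = 6L, nRegimes = 3L,
                          separability = 6,
                          skill = plantedSkill(nRegimes, mSolvers),
                          rmsdNoiseSd = 1, pbPassProb = 0.95,
                          proteinLenRange = c(30L, 60L),
                          dProtein = 64L, dLigand = 32L,
                          rmsdDist = c("truncnorm", "lognormal"),
                          seed = 0L) {
  rmsdDist <- match.arg(rmsdDist)
  if (!is.matrix(skill) || nrow(skill) != nRegimes ||
      ncol(skill) != mSolvers)
    stop("skill must be an nRegimes x mSolvers matrix")
  if (any(skill < 0)) stop("skill means must be >= 0")
  if (rmsdDist == "lognormal" && any(skill <= 0))
    stop("log-normal RMSD requires strictly positive skill means")
  if (is.matrix(pbPassProb)) {
    if (nrow(pbPassProb) != nRegimes || ncol(pbPassProb) != mSolvers)
      stop("pbPassProb matrix must be nRegimes x mSolvers")
  } else {
    pbPassProb <- matrix(pbPassProb, nRegimes, mSolvers)
  }
  if (any(pbPassProb < 0 | pbPassProb > 1))
    stop("pbPassProb must lie in [0, 1]")
  if (separability < 0) stop("separability must be >= 0")
  if (proteinLenRange[1] < 1) stop("minimum protein length is 1")
  if (nRegimes > min(dProtein, dLigand))
    stop("need nRegimes <= embedding dimension for orthogonal centroids")
  spec <- list(nInstances = as.integer(nInstances),
               mSolvers = as.integer(mSolvers),
               nRegimes = as.integer(nRegimes),
               separability = separability, skill = skill,
               rmsdNoiseSd = rmsdNoiseSd, pbPassProb = pbPassProb,
               proteinLenRange = as.integer(proteinLenRange),
               dProtein = as.integer(dProtein),
               dLigand = as.integer(dLigand), rmsdDist = rmsdDist,
               seed = as.integer(seed))
  class(spec) <- "SyntheticSpec"
  spec
}

#' Planted regime-by-solver skill matrix
#'
#' Each regime has one dominant solver with low mean RMSD and uniformly
#' poor alternatives — the separable-regimes scenario in which algorithm
#' selection has real headroom. Dominant solvers cycle through the
#' portfolio by default.
#'
#' @param nRegimes,mSolvers matrix dimensions.
#' @param dominantRmsd mean RMSD of the regime's dominant solver (Angstrom).
#' @param otherRmsd mean RMSD of all other solvers.
#' @param dominants integer vector, length nRegimes: dominant solver per
#'   regime.
#' @return nRegimes x mSolvers matrix.
#' @export
plantedSkill <- function(nRegimes, mSolvers, dominantRmsd = 0.5,
                         otherRmsd = 4,
                         dominants = ((seq_len(nRegimes) - 1L) %%
                                        mSolvers) + 1L) {
  sk <- matrix(otherRmsd, nRegimes, mSolvers)
  sk[cbind(seq_len(nRegimes), dominants)] <- dominantRmsd
  sk
}

## orthogonal centroid directions scaled so pairwise distance = delta
regimeCentroids <- function(nRegimes, d, delta) {
  if (delta == 0) return(matrix(0, nRegimes, d))
  G <- matrix(rnorm(d * nRegimes), d, nRegimes)
  Q <- qr.Q(qr(G))[, seq_len(nRegimes), drop = FALSE]
  t(Q) * delta / sqrt(2)
}

rtruncnorm0 <- function(n, mean, sd) {
  p0 <- pnorm(0, mean, sd)
  qnorm(p0 + runif(n) * (1 - p0), mean, sd)
}

#' Generate a synthetic benchmark
#'
#' Draws regimes, embeddings, RMSDs and PB flags per the spec and builds
#' the performance table through the scoring module. Fully deterministic
#' given the spec seed.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param scoring a \code{\link{ScoringConfig}}.
#' @return list of class \code{"SyntheticBenchmark"}: \code{instances}
#'   (\code{\link{InstanceSet}}), \code{table}
#'   (\code{\link{PerformanceTable}}), \code{regimes} (integer labels),
#'   \code{spec}.
#' @export
generateBenchmark <- function(spec, scoring = ScoringConfig()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  withLocalSeed(spec$seed, {
    n <- spec$nInstances
    m <- spec$mSolvers
    regimes <- sample.int(spec$nRegimes, n, replace = TRUE)
    centP <- regimeCentroids(spec$nRegimes, spec$dProtein,
                             spec$separability)
    centL <- regimeCentroids(spec$nRegimes, spec$dLigand,
                             spec$separability)
    lens <- sample(spec$proteinLenRange[1]:spec$proteinLenRange[2], n,
                   replace = TRUE)
    ids <- sprintf("cpx_%04d", seq_len(n))
    protein <- lapply(seq_len(n), function(i) {
      matrix(rnorm(lens[i] * spec$dProtein), lens[i], spec$dProtein) +
        matrix(centP[regimes[i], ], lens[i], spec$dProtein, byrow = TRUE)
    })
    ligand <- matrix(rnorm(n * spec$dLigand), n, spec$dLigand) +
      centL[regimes, , drop = FALSE]
    mu <- spec$skill[regimes, , drop = FALSE]
    rmsd <- if (spec$rmsdDist == "truncnorm") {
      matrix(rtruncnorm0(n * m, as.vector(mu), spec$rmsdNoiseSd), n, m)
    } else {
      sdlog <- spec$rmsdNoiseSd / mu       # coefficient-of-variation match
      matrix(stats::rlnorm(n * m, log(as.vector(mu)), as.vector(sdlog)),
             n, m)
    }
    pb <- matrix(rbinom(n * m, 1, as.vector(spec$pbPassProb[
      regimes, , drop = FALSE])), n, m)
    rownames(rmsd) <- ids
    pf <- Portfolio(sprintf("solver_%d", seq_len(m)))
    table <- PerformanceTable(rmsd, pb, pf, scoring)
    instances <- InstanceSet(ids, protein, ligand, "synthetic")
    out <- list(instances = instances, table = table, regimes = regimes,
                spec = spec)
    class(out) <- "SyntheticBenchmark"
    out
  })
}

#' Perturb a benchmark's protocol
#'
#' Emulates a post-processing/protocol change: each solver's RMSDs shift
#' by a per-solver amount (floored at 0 Angstrom) and its PB flags flip
#' with a per-solver probability. Embeddings and regimes are untouched;
#' scores and labels are recomputed through the scoring module. Small
#' shifts typically leave the global solver ranking highly correlated
#' while flipping the top-1 identity — the near-top reordering that breaks
#' cross-protocol transfer.
#'
#' @param bench a \code{"SyntheticBenchmark"}.
#' @param rmsdShift numeric, per-solver Angstrom shifts (recycled).
#' @param pbFlipProb numeric, per-solver flip probabilities (recycled).
#' @param seed seed for the flips.
#' @return a new \code{"SyntheticBenchmark"}.
#' @export
perturbProtocol <- function(bench, rmsdShift = 0, pbFlipProb = 0,
                            seed = 1L) {
  stopifnot(inherits(bench, "SyntheticBenchmark"))
  table <- bench$table
  m <- ncol(table)
  rmsdShift <- rep_len(rmsdShift, m)
  pbFlipProb <- rep_len(pbFlipProb, m)
  if (any(!is.finite(rmsdShift))) stop("shifts must be finite")
  rmsd <- SummarizedExperiment::assay(table, "rmsd")
  pb <- SummarizedExperiment::assay(table, "pbValid")
  rmsd2 <- pmax(sweep(rmsd, 2, rmsdShift, "+"), 0)
  pb2 <- withLocalSeed(seed, {
    flips <- matrix(rbinom(length(pb), 1,
                           rep(pbFlipProb, each = nrow(pb))),
                    nrow(pb), ncol(pb))
    abs(pb - flips)
  })
  out <- bench
  out$table <- PerformanceTable(rmsd2, pb2, portfolio(table),
                                scoringConfig(table))
  out
}

#' Write a benchmark fixture to disk
#'
#' Emits the pose-evaluation CSV, the embedding store and a YAML manifest
#' (keys: name, tables, embeddings, blocklist, regime, plus the solver
#' list and scoring lambda needed to reload) in the package's external
#' formats; \code{\link{loadBenchmark}} round-trips it.
#'
#' @param bench a \code{"SyntheticBenchmark"}.
#' @param directory output directory (created if needed).
#' @param name benchmark name.
#' @param regime \code{"separated"} (default) or \code{"mixed"}.
#' @return the manifest path, invisibly.
#' @export
writeFixture <- function(bench, directory, name = "synthetic",
                         regime = "separated") {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(directory, "table.csv")
  emb <- file.path(directory, "embeddings.rds")
  blk <- file.path(directory, "blocklist.txt")
  savePerformanceTable(bench$table, csv)
  writeEmbeddingStore(bench$instances, emb)
  writeLines(character(0), blk)
  pf <- portfolio(bench$table)
  manifest <- list(
    name = name, tables = "table.csv", embeddings = "embeddings.rds",
    blocklist = "blocklist.txt", regime = regime,
    solvers = lapply(seq_len(nSolvers(pf)), function(i) list(
      solver_id = solverIds(pf)[i], base_name = pf@baseNames[i],
      postprocess = pf@postprocess[i])),
    scoring = list(lambda = scoringConfig(bench$table)@lambda))
  path <- file.path(directory, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Load a benchmark from a manifest
#'
#' @param manifestPath path to a \code{manifest.yaml} written by
#'   \code{\link{writeFixture}} (or hand-authored with the same keys).
#' @return list: \code{name}, \code{regime}, \code{table}
#'   (blocklist already applied), \code{instances}.
#' @export
loadBenchmark <- function(manifestPath) {
  if (!file.exists(manifestPath))
    stop("manifest not found: ", manifestPath)
  man <- yaml::read_yaml(manifestPath)
  dir <- dirname(manifestPath)
  for (k in c("name", "tables", "embeddings", "blocklist", "regime"))
    if (is.null(man[[k]])) stop("manifest is missing key '", k, "'")
  csv <- file.path(dir, man$tables)
  emb <- file.path(dir, man$embeddings)
  blk <- file.path(dir, man$blocklist)
  for (p in c(csv, emb, blk))
    if (!file.exists(p)) stop("manifest references missing file: ", p)
  pf <- Portfolio(
    baseNames = vapply(man$solvers, `[[`, "", "base_name"),
    postprocess = vapply(man$solvers, `[[`, "", "postprocess"),
    solverIds = vapply(man$solvers, `[[`, "", "solver_id"))
  lambda <- if (!is.null(man$scoring$lambda)) man$scoring$lambda else 3
  table <- loadPerformanceTable(csv, pf, ScoringConfig(lambda = lambda))
  blocklist <- readLines(blk)
  blocklist <- blocklist[nzchar(blocklist)]
  if (length(blocklist))
    table <- applyBlocklist(table, blocklist)
  instances <- readEmbeddingStore(emb)
  instances <- subsetInstances(instances, instanceIds(table))
  list(name = man$name, regime = man$regime, table = table,
       instances = instances)
}
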