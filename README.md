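# DockSelect

Instance-wise algorithm selection for protein–ligand docking portfolios,
driven by precomputed molecular embeddings.

## The problem

No single docking engine wins on every complex: classical scoring/search
pipelines, diffusion-based pose generators and co-folding frameworks each
dominate in different structural regimes. Given a portfolio
𝒜 = {A₁, …, A_m} of docking pipelines and per-complex performance labels,
an algorithm-selection (AS) system is a mapping S : 𝒳 → 𝒜 realised as

    S = argmax ∘ g ∘ f

where `f` encodes a complex **x** = (x_P, x_L) — a residue-level protein
embedding matrix x_P ∈ ℝ^(|residues|×1152) (e.g. from a protein language
model) and a pooled ligand embedding x_L ∈ ℝ^384 (e.g. from a SMILES
transformer) — and `g` predicts one calibrated score per solver. The
selector is deliberately lightweight: a learned-query attentional pooler
compresses x_P into one protein vector, the fused [protein; ligand] pair is
projected to a 128-dim joint space, and a stack of residual blocks
(linear → batch norm → ReLU → linear, with skip connections; block outputs
concatenated) feeds a linear head with one sigmoid output per solver.

Supervision is the **gated composite pose score**

    s(x; λ) = (1 + e^(−2λ)) / (1 + e^(λ(x − 2))) · s_PB,

a smooth, strictly decreasing sigmoid of the pose RMSD x (Å), centred at
the 2 Å validity threshold where its gradient is maximal (λ = 3 by
default), multiplied by the binary PoseBusters-validity gate s_PB so that
chemically implausible poses score 0 regardless of geometry. Reporting
uses the *strict* (RMSD ≤ 1 Å & PB-valid) and *relaxed* (RMSD ≤ 2 Å &
PB-valid) success criteria, and the standard AS baselines: the **SBS**
(single best solver — highest mean performance), the **VBS** (per-instance
oracle) and the **gap closed**, 100·(AS − SBS)/(VBS − SBS). Diagnostics
cover Selected@K / VBS@K, selection-collapse detection, margin-based
reliability (12 equal-mass bins), oracle entropy, and protocol-stability
statistics (Spearman ρ, tie-corrected Kendall τ_b, top-k Jaccard overlap
curves).

Everything is exercisable offline through a synthetic benchmark generator
that plants latent solver regimes in embedding space with controllable
separability, VBS–SBS gap and oracle entropy.

## Worked example

Generate a benchmark with three planted regimes (each with its own
dominant solver), train a selector on four folds, and evaluate selection
on the held-out fold:

```r
library(DockSelect)

spec  <- syntheticSpec(nInstances = 600, mSolvers = 6, nRegimes = 3,
                       separability = 6, seed = 0)
bench <- generateBenchmark(spec)
bench$table
#> PerformanceTable: 600 instances x 6 solvers
#>   missing cells: 0
#>   mean relaxed success per solver: 0.327 0.292 0.268 0.028 0.022 0.023
vbsEntropy(bench$table)
#> [1] 1.864

folds <- makeKFold(instanceIds(bench$table), k = 5, seed = 1)
fit   <- trainSelector(bench$table, bench$instances, folds, fold = 0,
                       tConfig = trainConfig(maxEpochs = 40, patience = 8,
                                             seed = 1))
pred  <- predictSolvers(fit$model,
                        subsetInstances(bench$instances, fit$valIds))
evaluateSelections(pred$selected, bench$table[fit$valIds, ])
#> strict   SBS 0.2167 (solver_2) | selector 0.5083 | VBS 0.5083 | gap closed 100.00% | p = 5.82e-11
#> relaxed  SBS 0.3500 (solver_2) | selector 0.8167 | VBS 0.8500 | gap closed 93.33% | p = 4.09e-16
```

The static SBS succeeds on 35% of held-out complexes under the relaxed
criterion; the trained selector reaches 81.7% against an oracle ceiling of
85%, closing 93% of the VBS–SBS gap (exact sign test p ≈ 4×10⁻¹⁶). The
oracle entropy of 1.86 bits (of log₂6 ≈ 2.58 possible) confirms a
genuinely multi-modal selection problem. With `separability = 0` the
embeddings carry no regime signal and the same pipeline collapses to an
SBS-like policy with gap closure near zero — the documented operational
boundary of embedding-based docking AS.

A thin command-line wrapper over the same functions is included:

```sh
Rscript inst/scripts/docksel.R simulate --seed 0 --out run/
Rscript inst/scripts/docksel.R train --manifest run/manifest.yaml --out run/
Rscript inst/scripts/docksel.R evaluate --manifest run/manifest.yaml --out run/report.json
```

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the model and
its assumptions, the scoring and training objectives, what the synthetic
generator does and does not emulate, all numerical choices, and known
limitations.
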