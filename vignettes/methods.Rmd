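---
title: "Embedding-based algorithm selection for docking portfolios: models and methods"
author: "DockSelect authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedding-based algorithm selection for docking portfolios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DockSelect)
```

# The selection problem

Given a portfolio $\mathcal{A} = \{A_1,\dots,A_m\}$ of docking pipelines
and a set of protein–ligand complexes, per-instance algorithm selection
learns a mapping $S = \arg\max \circ g \circ f$ that predicts, for each
complex, a performance score per solver and selects the argmax. The
baselines that bracket any selector are the *single best solver* (SBS,
the highest mean-performance column) and the *virtual best solver* (VBS,
the per-instance row maximum); the fraction of the VBS–SBS gap closed,
$100\,(\mathrm{AS}-\mathrm{SBS})/(\mathrm{VBS}-\mathrm{SBS})$, is the
headline metric because absolute success rates conflate portfolio quality
with selection quality.

Inputs are *precomputed* embeddings: a residue-level protein matrix
(default width 1152) and a pooled ligand vector (default length 384).
Embedding extraction, RMSD computation and the 18 physical-plausibility
checks are all upstream concerns; the package consumes their outputs as
tabular data, which keeps the selector testable without any chemistry
toolkit and makes the supervision protocol explicit.

# The gated composite score

Pose quality is scored by
$$ s(x;\lambda) = \frac{1+e^{-2\lambda}}{1+e^{\lambda(x-2)}}, \qquad
   s = s(x;\lambda)\, s_{\mathrm{PB}}, $$
where $x$ is the pose RMSD in Å and $s_{\mathrm{PB}} \in \{0,1\}$ the
PoseBusters-validity gate. The sigmoid is centred at the conventional
2 Å geometric-validity threshold, where its gradient magnitude peaks, so
borderline improvements are rewarded most strongly; the numerator makes
$s(0) = 1$ exactly. Unlike hard-threshold scores it never clips to zero,
so moderately poor poses remain ordered — informative for ranking-aware
objectives. $\lambda$ (unitless, default 3, ablation values 1 and 5)
controls sensitivity around the centre.

Numerical choices: the score is evaluated in log space
(`log1p` / stable `log1pexp`), so it underflows gracefully (at
$x = 10,\ \lambda = 3$ it is $\approx 4\times10^{-11}$, still positive);
RMSD may be exactly 0 (self-pose), with no epsilon floor; a *missing* PB
flag is a hard error, never an implicit pass or fail, because silent
coercion would bias every composite score downstream. Success criteria
are inclusive: strict means RMSD $\le 1$ Å, relaxed RMSD $\le 2$ Å, both
requiring PB-validity — inclusivity matters for boundary poses at exactly
1.0 or 2.0 Å.

# Data model

`PerformanceTable` extends `SummarizedExperiment`: rows are complexes,
columns are portfolio solvers, assays hold raw RMSD/PB values and the
derived score and success matrices, and `colData` carries the solver
configurations (base pipeline × post-processing tag). Cells with no
recorded pose — a docking engine failing on a complex, a case real
benchmarks do exhibit but rarely document — receive composite score 0 and
success 0 (a solver that produces no pose cannot succeed), with an
explicit missing-mask retained for sensitivity analyses.

Portfolio order is the global tie-break priority: argmax ties, equal
selection frequencies and top-$k$ set construction all resolve to the
earliest index, which makes every reported number reproducible. "Mixed"
post-processing regimes widen the portfolio (each base pipeline appears
once per variant as a distinct solver) rather than duplicating instances;
this matches reporting conventions in which a pipeline and its relaxed
variant are ranked as separate solvers, and it keeps one row per complex.

The embedding store is a single RDS container keyed by instance id, each
key holding the residue matrix and ligand vector; benchmark manifests are
YAML (`name`, `tables`, `embeddings`, `blocklist`, `regime`, plus the
solver list and scoring λ needed to reload), with blocklists as plain
id lists — the mechanism for excluding training-corpus overlaps from an
evaluation split. Pose evaluations travel as CSV
(`instance_id,solver_id,postprocess,rmsd,pb_valid`), written with 17
significant digits so round trips are bit-exact.

# Curation filters

The two-stage complex filter retains proteins composed exclusively of the
20 canonical one-letter residues (ambiguity codes B/Z/X and noncanonical
U/O all fail) and ligands satisfying the Lipinski-style thresholds
MW $\le 500$ Da, $\log P \le 5$, HBD $\le 5$, HBA $\le 10$, all
inclusive. Descriptor computation is an adapter's job (including the
choice of $\log P$ dialect, e.g. Crippen); the filter consumes numeric
records, and a rejection report lists each removed complex with the first
failed criterion in a fixed order (protein, then MW, logP, HBD, HBA).
Dataset-specific housekeeping of raw archives (duplicate/incomplete
entries) is out of scope because it is not reproducible from published
descriptions.

# Selector architecture

Per attention head $h$ (default 1; $d_{\text{head}} = d_P/\text{heads}$):
a learned query vector $q_h$, key and value projections
$W_k^h, W_v^h \in \mathbb{R}^{d_{\text{head}}\times d_P}$, attention
weights $\alpha_i = \mathrm{softmax}_i\!\big(q_h\!\cdot\!W_k^h x_i /
\sqrt{d_{\text{head}}}\big)$ over residues, pooled head output
$\sum_i \alpha_i W_v^h x_i$, heads concatenated back to $d_P$. There is
no positional encoding, so pooling is permutation-invariant by
construction (a tested property). These pooler internals are a design
choice of this package — published descriptions of attentional poolers at
this level of detail are typically silent on them — and the parameter
count is therefore reported by `nParams()` as an order-of-magnitude
sanity quantity, not matched to any external figure.

The pooled protein vector is concatenated with the ligand embedding and
linearly projected to a joint dimension of 128 (inferred from the
decoder's stated input width). The decoder default is **4** residual
blocks of width 256 — prose descriptions of this architecture family say
"three", but the ablation baseline is labelled with four, and we adopt
the configuration the ablations perturb around, with 3 reachable via
`selectorConfig(nBlocks = 3)`. Each block computes
$z + W_2\,\mathrm{ReLU}(\mathrm{BN}(W_1 z))$; block outputs (and only
they) are concatenated into the final linear head, one logit per solver.
Outputs are independent sigmoids, not a softmax: several solvers can
legitimately score high on the same complex, and multi-label calibration
avoids forcing competition.

Batch normalisation uses batch statistics during training and running
averages (momentum 0.1, $\varepsilon = 10^{-5}$) at inference, so
batch-size-1 prediction is well defined; trailing training batches of
size 1 are skipped. Initialisation is fan-in uniform for all linear maps,
zero biases, unit BN scales, fully seeded — identical configs produce
bit-identical parameters and forward passes. Modality-dropout variants
(`protein_only`, `ligand_only`) zero the dropped embedding before fusion,
for ablating single-modality shortcuts.

The forward and backward passes are implemented directly as vectorised
matrix operations (residues of a whole batch are stacked and pooled via
grouped softmax), with analytic gradients for every parameter; the test
suite checks them against central differences to $10^{-4}$ (they agree to
$\sim10^{-9}$ in practice).

# Training objectives

The primary loss is binary cross-entropy with logits against the
composite-score targets, computed in softplus form for stability and
supporting soft labels. Auxiliaries, combinable through non-negative
`lossMix` weights: MSE on sigmoid outputs; pairwise logistic loss over
ordered pairs whose targets differ by more than $\tau_{\text{tie}} =
10^{-6}$ (near-ties are excluded as they carry label noise, a documented
failure mode of ranking supervision on shallow oracles); and a smooth
NDCG@3 surrogate built from temperature-parameterised soft ranks
(temperature 1.0; soft top-3 membership via a sigmoid of
$k + \tfrac12 - \text{rank}$), which approaches $1 - \mathrm{NDCG@3}$ as
the temperature goes to 0. Uniform targets yield zero ranking loss (any
order is ideal).

Optimisation: Adam (defaults $10^{-3}$, $\beta = (0.9, 0.999)$), batch
size 64, cosine learning-rate schedule spanning `maxEpochs` with no
restarts, early stopping with patience 20 of 200 epochs by default.
"Validation accuracy" for early stopping is taken as the held-out fold's
top-1 selection success rate under the relaxed criterion — the headline
reported metric — since published descriptions leave it unspecified; the
best-epoch parameters and BN statistics are restored. The in-domain
protocol is a seeded 5-fold split (deterministic shuffle, round-robin
assignment, 8–2 train–test per fold), with out-of-fold selections
stitched so each complex is evaluated by a model that never saw it.

Selector-vs-SBS significance uses an exact two-sided sign test on the
paired per-instance success indicators (binomial at $p = \tfrac12$ over
discordant pairs; $p = 1$ with none). The test identity is again
unspecified in published descriptions; the sign test is the canonical
choice for paired binary outcomes, and the per-instance success vectors
are exposed so alternatives can be substituted.

# Evaluation and diagnostics

Beyond SBS/VBS/gap closure: `vbsAtK` (per-instance $k$-th order
statistic) quantifies how flat the oracle is near the top;
`selectedAtK` ranks solvers by selection frequency; `vbsEntropy` is the
Shannon entropy (bits) of the oracle-winner distribution with exact ties
splitting mass fractionally — 0 bits means one solver dominates and
selection has no headroom. "Oracle agreement" counts a selection as
correct when it attains the row maximum (any tied maximum counts),
matching the flat-near-the-top reading of shallow oracles; the
fractional-mass convention affects entropy and frequency panels and is
therefore fixed and documented. `marginReliability` sorts predictions by
the top-1/top-2 probability margin into equal-mass bins (default 12,
remainder to the lowest bins, deterministically) and reports oracle
agreement and strict/weak advantage over the SBS per bin.

`rankStability` compares two protocols over the same portfolio via the
solver rankings induced by mean per-solver *composite scores* (the
success-indicator variant is available through `metric`): Spearman ρ on
average ranks, tie-corrected Kendall $\tau_b$ (implemented by explicit
concordance counting and cross-checked in tests against an independent
reference), and top-$k$ Jaccard overlaps $J_k$ for $k = 1..m$ with
deterministic index tie-breaks, summarised by $J_1$ and $\bar J$. The
characteristic phenomenon — global correlation high while the top-1
identity flips ($\rho > 0.9$, $J_1 = 0$) — is reproduced by the synthetic
protocol-perturbation operator.

`gapClosed` returns `NA` (with a warning), never $\pm\infty$, on
degenerate benchmarks where VBS = SBS, and errors if VBS < SBS since the
oracle cannot underperform a fixed column.

# The synthetic generator

`syntheticSpec`/`generateBenchmark` emulate the statistical structure of
a docking AS benchmark: instances are assigned uniformly to latent
regimes; regime centroids are placed $\delta$ noise-SDs apart along
orthogonal directions (so $\delta$ is exactly the centroid separation) in
both the protein and ligand embedding spaces; residue vectors are drawn
per-residue around the centroid with unit isotropic noise (variable
protein lengths, default 30–60 residues, exercise the pooler
realistically); RMSDs follow a zero-truncated normal around the
regime-by-solver skill means (truncation keeps the support physical and
its tail probabilities are available in closed form for oracle tests; a
log-normal alternative is provided); PB flags are Bernoulli. Defaults
use small embedding dimensions (64/32) so the suite stays fast; the full
1152/384 are a parameter away.

The planted-skill default gives each regime one dominant solver
(mean RMSD 0.5 Å versus 4.0 Å, PB pass 0.95, noise SD 1.0 Å), under
which the oracle winner matches the plant on ≥ 90% of instances, and a
selector trained on four folds closes well over half of the relaxed
VBS–SBS gap on the held-out fold. With $\delta = 0$ the embeddings are
uninformative while the oracle gap persists, and training converges to an
SBS-like policy — the no-pathology control. Test and acceptance runs use
1500 instances, 6 solvers and 3 regimes for the study conditions, 600–800
instances for diagnostics, and 2000–10000 draws for distributional
checks; these sizes make the Monte-Carlo tolerances in the tests
comfortable.

What the generator does **not** emulate: structural realism of
embeddings (no sequence or chemistry underlies them), correlated solver
errors within a complex, heavy-tailed RMSD behaviour of real engines, or
engine failure patterns. Passing tests therefore demonstrate the
correctness of the selection machinery and its learnability properties on
separable regimes — not that real benchmarks are separable, which is an
empirical property of the docking workflow that defines them.

# Known limitations

* Cross-protocol transfer is intrinsically limited: supervision is
  defined by a workflow's score landscape, and the package's own
  perturbation diagnostics show how small protocol shifts reorder the
  upper tail of the solver hierarchy. The cross-benchmark evaluation mode
  requires identical portfolios and makes no invariance claim.
* Batch-norm statistics make training mildly batch-order dependent;
  all of it is seeded, so runs are exactly reproducible, but changing
  the batch size changes the trajectory.
* The embedding store uses R serialisation (RDS); it is a container
  choice behind `writeEmbeddingStore`/`readEmbeddingStore`, and swapping
  in another keyed hierarchical format only touches those two functions.
* The pairwise and NDCG losses are $O(m^2)$ per instance; fine for
  portfolios up to the 48-solver mixed regime, but quadratic beyond.
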