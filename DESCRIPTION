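Package: DockSelect
Title: Embedding-Based Algorithm Selection for Protein-Ligand Docking Portfolios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Instance-wise selection of docking algorithms from a solver
    portfolio using precomputed protein residue embeddings and ligand
    embeddings. Implements a gated composite pose score (a sigmoid transform of
    symmetry-corrected RMSD gated by PoseBusters validity), a lightweight
    selector built from an attentional pooler over residue embeddings, a
    protein-ligand fusion layer and a residual MLP decoder, multi-label
    training objectives (binary cross-entropy with logits plus MSE, pairwise
    logistic and NDCG@3 auxiliaries), algorithm-selection evaluation metrics
    (single best solver, virtual best solver, gap closure, Selected@K, VBS@K),
    rank-stability diagnostics (Spearman's rho, Kendall's tau-b, top-k Jaccard
    overlap, oracle entropy), Lipinski-style dataset curation filters, and a
    synthetic benchmark generator with planted solver regimes for end-to-end
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'utils.R'
    'scoring.R'
    'portfolio.R'
    'performance-table.R'
    'instances.R'
    'curation.R'
    'losses.R'
    'selector.R'
    'train.R'
    'evaluation.R'
    'synthetic.R'
    'cli.R'
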