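Package: repdiv
Title: Diversity, Overlap and Composition Analysis of TCR-Beta Repertoires
Version: 0.1.0
Authors@R: person("repdiv", "maintainers", email = "repdiv@example.org", role = c("aut", "cre"))
Description: Tools for characterizing T-cell receptor beta-chain (TRB) CDR3
    clonotype repertoires from UMI-based sequencing. Reads AIRR Rearrangement
    and MiXCR-style clonotype tables, normalizes repertoires to fixed UMI
    depths by hypergeometric subsampling, and computes diversity statistics
    (Shannon, Simpson, D50, Chao1, Top100, Hill number curves, rank-abundance
    profiles), V/D/J segment usage and combination matrices, pairwise
    repertoire overlap (overlap coefficient, F2, R, D), CDR3 amino-acid
    composition with Bhattacharyya distances and self-reactivity indices
    (hydrophobic doublet and cysteine indices), and CDR3 length spectratype
    summaries (complexity score, skewness). Includes cohort-level machinery
    (feature assembly, PCA, group tests with multiplicity correction), a
    synthetic V(D)J repertoire simulator with known ground truth, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
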