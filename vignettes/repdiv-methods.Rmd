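---
title: "Methods: repertoire diversity, overlap and composition in repdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repertoire diversity, overlap and composition in repdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repdiv)
```

# Scope and data model

`repdiv` analyzes TRB CDR3 clonotype tables produced by UMI-based
repertoire sequencing pipelines. The unit record is the **clonotype**: a
CDR3 nucleotide sequence with V/D/J gene calls, an amino-acid
translation, and a UMI count. A **repertoire** is one sample's clonotype
collection plus metadata (group, cell subset). The package consumes
clonotype tables, not reads: UMI consensus building and error correction
are upstream concerns.

Three conventions anchor everything downstream:

- **Clonotype species (`key_mode`)**: analyses that intersect or merge
  clonotypes must fix what "the same clonotype" means. The default
  species for the overlap coefficient is the CDR3 nucleotide sequence
  alone (`nt`); usage-aware analyses and the F2/R/D metrics default to
  nucleotide + V + J (`nt_vj`, the strict convention of overlap
  software); an amino-acid mode (`aa`) exists for convergence analyses.
  Every result records the mode used.
- **CDR3 coordinates**: the CDR3 includes the conserved cysteine at
  position 1 and the conserved phenylalanine at the last position;
  positional indices (e.g. the 6–7 doublet) are 1-based from that
  cysteine.
- **Productivity**: by default only productive clonotypes (in-frame,
  stop-free junctions whose translation matches the reported amino-acid
  sequence) are retained, because the analyses target expressed mRNA
  repertoires. Whether upstream tools pre-filter is not always knowable,
  so `productive_only` is exposed on every reader.

UMI counts are the only abundance unit; there is no read-level weighting
anywhere.

# Depth normalization

Diversity indices are depth-sensitive, so samples are compared after
random subsampling to fixed UMI depths (default ladder 4,000 / 6,000 /
8,000 / 10,000 / 12,000). Sampling is **without replacement** from the
multiset of observed molecules — a multivariate hypergeometric draw,
implemented as a chain of univariate `rhyper` conditionals — because
UMIs are physical molecules; multinomial resampling would inflate
variance. Consequences that the tests assert: the subsampled total is
exact, no clonotype exceeds its original count, and depth = total
reproduces the input identically. Samples shallower than a requested
depth are skipped for that depth with a logged warning, never upsampled.
The replicate count per depth defaults to 10 with replicate means
reported; one-draw-per-depth analyses are a degenerate case
(`replicates = 1`).

# Diversity statistics

All indices operate on the clonotype count vector. Shannon entropy uses
the natural logarithm, so the Hill identity exp(H) = ¹D holds exactly.
Because "Simpson index" denotes D = Σ pᵢ² in some reports and 1 − D in
others — and the two move in opposite directions under clonal
expansion — `simpson()` returns both, and every table labels the form.
D50 is the percentage of top-ranked unique clonotypes needed to reach
half of all sequences, with the boundary resolved by strict
"cumulative ≥ 0.5"; ties among equal counts are broken by the
repertoire's stable sort (count descending, then key), so results are
reproducible. Chao1 uses the classic estimator with the bias-corrected
form when no doubletons exist (configurable to always); singletons and
doubletons are defined on UMI counts. Hill curves default to q ∈ [0, 8]
in steps of 0.25 — wide enough to span richness-dominated through
dominance-dominated regimes; the grid is configurable.

Properties the suite enforces rather than assumes: scale invariance of
all indices except Chao1 under integer count scaling, the coarsening
inequality (merging clonotypes cannot increase H or 1 − D), Hill
monotonicity in q, and agreement with brute-force oracles (and vegan,
independently) to 1e-9.

# Segment usage and group comparison

Usage tables are frequencies over genes (or V–J / V–D–J tuples) under
two weightings: `total` (UMI-weighted) and `unique` (per-clonotype).
Clonotypes without a D call — common, since D is short and heavily
trimmed — are pooled into an explicit `unassigned` bin so every table
sums to 1; combination tables marginalize exactly onto their axis
tables, which is tested as an identity.

`compare_usage` runs one test per gene present in either group, entering
absent genes at frequency 0. Per-sample t or Wilcoxon tests treat the
mouse (sample) as the unit of replication; a pooled χ² mode tests
gene-versus-rest counts when per-sample replication is unavailable. The
default multiplicity correction is Benjamini–Hochberg across the genes
of one axis; a Dunnett-style correction is provided for fidelity with
common multiple-t workflows and is realized through a Monte-Carlo
max-|t| reference distribution (independent t-variates), since no
multivariate-t package is assumed. Degenerate cases (zero variance in
both groups) are flagged, not crashed.

# Overlap metrics

The overlap coefficient |X∩Y|/min(|X|,|Y|) is computed on clonotype key
sets, nucleotide species by default. F2, R and D follow the conventions
of the established overlap software: F2 = Σ√(fₓf_y) over shared
clonotypes (the repertoire share occupied by common clonotypes), R is
the Pearson correlation of log₁₀ frequencies of shared clonotypes
(undefined below two shared clonotypes, flagged rather than propagated
as NaN), and D = n_shared/(|X|·|Y|). Heatmap distances are
1 − overlap_coefficient (or 1 − F2); the choice is recorded in output
metadata because "distance" is otherwise underdetermined. All metrics
are validated against set/sum/correlation oracles on hundreds of random
pairs to 1e-12.

# Amino-acid composition and self-reactivity indices

Composition vectors pool residues over productive CDR3s (UMI-weighted by
default). Sample similarity uses the Bhattacharyya distance
BD = −ln Σ√(pq); identical compositions give 0, disjoint supports give
+Inf, and no triangle inequality is claimed.

Two self-reactivity indices follow the doublet/cysteine convention of
the T-cell tolerance literature:

- **Hydrophobic index**: the fraction of 13-residue CDR3s (the canonical
  spectratype mode for positional analysis) whose positions 6 and 7 form
  a hydrophobic doublet. The promoting-doublet set is data, not code:
  the default counts both residues in the strongly hydrophobic class
  {A, C, F, I, L, M, V, W, Y}, and any curated pair list can be passed
  instead. Growing the set can only increase the index (tested).
- **Cysteine index**: the fraction of CDR3s containing a cysteine within
  2 residues of the CDR3 apex (midpoint anchoring, chosen because
  self-reactivity work centers on the loop apex; start/end anchoring are
  configurable), excluding the invariant position-1 cysteine.

Both are UMI-weighted by default, matching total-sequence analyses; a
unique-sequence mode exists.

# Spectratype

CDR3 length histograms are exact nucleotide-length bins (an amino-acid
mode divides by three for productive clonotypes). The **complexity
score** is operationalized as the number of length bins at or above a
frequency threshold (default 1%), the spectratyping peak-count
convention — the literature names this score without giving a formula,
so the thresholded-bin surrogate is an explicit, recorded choice.
**Skewness** is the third standardized moment of the frequency-weighted
length distribution, population form (no sample correction), because
the histogram describes the entire repertoire rather than a sample of
lengths; single-length distributions return 0 with a degenerate flag.

# Cohort statistics

The default feature matrix carries the four summary variables (Shannon,
Simpson diversity, total and unique sequence counts). Features are
z-scored before PCA because the counts live on different scales than
the indices; a `log10` transform for count features is available since
raw-versus-log is genuinely open. PCA orientation is made deterministic
by forcing the largest-magnitude loading entry of each component
positive, so repeated runs are bit-comparable. Zero-variance features
are dropped with a warning rather than producing NaNs.

# The synthetic repertoire generator

`simulate_repertoire` builds clonotypes as V-stub + N1 + trimmed-D + N2
+ J-stub, with segments drawn from configurable usage weights, geometric
trims (mean 4 nt per end), Poisson inserts (mean 4 nt, GC-biased), and
rejection of unproductive junctions. The nucleotide stubs are
**synthetic stand-ins, not IMGT germline sequences**: V cores open with
the conserved TGT cysteine codon, J cores end on a phenylalanine codon,
and trimming never invades these anchors. This stub-based design was
chosen over germline reconstruction because no downstream analysis needs
genomic coordinates — only realistic clonotype tables. Defaults produce
CDR3 lengths centered near 13–15 amino acids with the 13-mer class well
populated for positional analyses.

Clone sizes come from a configurable law: `uniform` and `geometric`
(p = 0.5) give even, wild-type-like repertoires; `powerlaw` (Zipf
exponent 1.5) and `lognormal` give expanded ones. The law list includes
`uniform` — needed for saturation and Chao1-recovery checks — in
addition to the skewed laws. Depth defaults to 12,000 UMIs, the deepest
standard rarefaction level, allocated multinomially across clone-size
weights. Generated clonotypes are forced key-distinct (collisions are
regenerated within the retry cap, 50 rounds) so the ground-truth
richness is exact.

`simulate_cohort` derives per-sample seeds deterministically from the
base seed and applies group effects: additive V-usage shifts
(renormalized — note this makes *other* genes genuinely shift slightly
in the opposite direction) and clone-size overrides. Per-sample depth is
jittered lognormally (CV 0.15 by default) because real sequencing yields
vary; without this, summary features such as total and unique sequence
counts would be degenerate across simulated samples.

**What a green test does and does not establish.** The simulator
emulates segment-usage skew, junctional diversity, clonal expansion and
depth variation — the statistical structure the analyses consume. It
does **not** model public (shared) clonotypes: independently simulated
samples share essentially no sequences, so overlap metrics are validated
on constructed pairs and brute-force oracles rather than on simulated
cohorts. It also does not model thymic selection, pMHC binding, or
sequencer error profiles. Passing tests certify the statistical
machinery on data with known truth, not the biology of any particular
mouse experiment.

# Numerical and design choices

- Natural-log Shannon; exp(H) = ¹D to 1e-9 (tested identity).
- q = 1 Hill numbers evaluated as the analytic limit, with |q − 1| <
  1e-12 treated as 1.
- Bhattacharyya coefficient clamped to [0, 1] before −ln to absorb
  floating-point overshoot; composition inputs validated to sum to 1
  within 1e-6.
- Repertoire tables are stored sorted (count descending, then key), so
  merging is order-independent and output files are deterministic.
- Seeds: every stochastic entry point takes a seed; derived seeds use a
  fixed integer map kept inside 32-bit range; RNG state of the caller is
  always restored.
- Empty repertoires raise undefined-statistic errors rather than
  returning NaN; degenerate statistics (single shared clonotype for R,
  single-length spectratype) return flagged values.
- The pipeline manifest records every configurable decision in effect
  (key modes, thresholds, weightings, correction method, seed) and
  contains no timestamps, making reruns byte-identical.

# Known limitations

- The complexity score is a surrogate (thresholded peak count); scores
  from tools using a different definition are not numerically
  comparable.
- Dunnett correction assumes independent test statistics in its
  Monte-Carlo reference; correlated usage frequencies make it mildly
  conservative or liberal depending on the correlation sign.
- Chi-squared usage comparison pools counts across samples and therefore
  ignores between-mouse variation; prefer the per-sample tests when
  replication allows.
- No coverage-based (iNEXT-style) richness extrapolation beyond Chao1;
  no confidence intervals for Chao1.
- MiXCR dialect support takes the best hit per gene column and ignores
  alignment scores.
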