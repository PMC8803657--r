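# repdiv

Characterization of T-cell receptor β-chain (TRB) CDR3 clonotype
repertoires from UMI-based high-throughput sequencing, for immunologists
comparing repertoire diversity, segment usage and sequence composition
across cell subsets or genotypes (e.g. wild-type versus knock-out memory
T-cell compartments).

## What it computes

Given clonotype tables (AIRR Rearrangement TSV or a MiXCR/miTCR-style
dialect), `repdiv` provides:

- **Depth normalization** — exact multivariate-hypergeometric subsampling
  of UMIs to fixed depths (default ladder 4,000–12,000), with replicate
  rarefaction curves.
- **Diversity and clonality** — Shannon–Wiener H = −Σ pᵢ ln pᵢ, Simpson
  D = Σ pᵢ² (both D and 1−D reported, always labelled), D50, Chao1
  (S_obs + f1²/2f2, bias-corrected when f2 = 0), Top100, Hill numbers
  ^q^D = (Σ pᵢ^q)^{1/(1−q)} over a q grid, rank-abundance and cumulative
  clonotype curves.
- **V/D/J usage** — per-gene and V–J/V–D–J combination frequency tables on
  total (UMI-weighted) and unique sequences, with per-gene group tests
  (t, Wilcoxon, χ²; BH/Bonferroni/Dunnett-style correction).
- **Repertoire overlap** — the overlap coefficient
  |X∩Y|/min(|X|,|Y|) on CDR3 nucleotide species, plus the VDJTOOLS-style
  F2 (Σ√(fₓf_y) over shared clonotypes), R (Pearson correlation of shared
  log₁₀ frequencies) and D (n_shared/(|X|·|Y|)) metrics, and 1−overlap
  distance matrices.
- **Amino-acid features** — CDR3 residue composition, Bhattacharyya
  distance BD = −ln Σ√(p·q) between samples, hydrophobic doublet index at
  CDR3 positions 6–7 of 13-mers, cysteine index (C within 2 residues of
  the CDR3 apex), positional composition.
- **Spectratype** — CDR3 nucleotide-length histograms with complexity
  score (peaks ≥ 1%) and frequency-weighted skewness.
- **Cohort machinery** — feature matrices (Shannon, Simpson, total and
  unique sequence counts, or per-gene usage), deterministic PCA, group
  tests.
- **Simulation** — a stub-based V(D)J recombination generator with known
  ground truth (segment-usage weights, junctional trimming/insertion,
  clone-size laws from even to power-law-expanded, UMI depth), used
  throughout the test suite.

## Worked example

```r
library(repdiv)

cfg <- simulation_config(seed = 1L, n_clonotypes = 2000L, depth = 12000L)
coh <- simulate_cohort(cfg, n_per_group = 3L,
                       effects = list(KO = list(clone_size_law = "powerlaw")))

diversity_profile(coh[["WT_CD4_TEM_01"]])
#> <diversity_profile> WT_CD4_TEM_01: richness 1948, Shannon 7.3111,
#>   Simpson 1-D 0.9992, D50 23.3%, Chao1 2014.9, Top100 16.9%
diversity_profile(coh[["KO_CD4_TEM_01"]])
#> <diversity_profile> KO_CD4_TEM_01: richness 479, Shannon 2.8973,
#>   Simpson 1-D 0.8173, D50 0.4%, Chao1 845.3, Top100 94.3%
```

The power-law "KO" sample shows the signature of clonal expansion: far
lower D50 (0.4% of unique clonotypes already hold half of all UMIs,
versus 23.3% in the even "WT" sample), lower 1−D, and a Top100 share of
94.3% versus 16.9%.

```r
sh  <- vapply(coh, shannon, numeric(1))
grp <- vapply(coh, function(r) r$group, character(1))
group_test(sh[grp == "WT"], sh[grp == "KO"])
#> Shannon WT vs KO: t = 170.65, p = 1.178e-05
```

Reading real data and normalizing depth:

```r
rep <- read_airr("sample1.airr.tsv", group = "WT", subset = "CD4_TEM")
rep4k <- subsample(rep, 4000L, seed = 17L)
usage(rep4k, "V", weighting = "total")
```

## Command line

```sh
Rscript -e 'repdiv::repdiv_cli()' simulate --seed 4 --n-clonotypes 1000 --out sim.airr.tsv
Rscript -e 'repdiv::repdiv_cli()' subsample --depth 4000 --seed 17 sim.airr.tsv sub.airr.tsv
Rscript -e 'repdiv::repdiv_cli()' diversity --indices shannon,simpson,d50 sub.airr.tsv
Rscript -e 'repdiv::repdiv_cli()' run --config pipeline.json
```

(`inst/scripts/repdiv` is an equivalent installed launcher.) The `run`
subcommand executes the whole pipeline — read/simulate, rarefy,
diversity, usage, overlap, amino-acid features, spectratype, PCA, group
comparisons — and writes tidy TSV tables plus a `manifest.json`
recording the seed and every analysis setting; reruns with the same
configuration are byte-identical.

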