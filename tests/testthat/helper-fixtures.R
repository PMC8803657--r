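# Deterministic toy repertoires built in code.
#
# Junctions are valid productive CDR3s: conserved TGT (C) start, TTT (F)
# end, with a stop-free codon body encoding the clonotype index so every
# index yields a distinct nucleotide sequence.

.codon_digits <- c("GCA", "TGC", "GAC", "GAA")  # A C D E

toy_junction <- function(i) {
  digits <- integer(4)
  x <- i - 1
  for (k in 4:1) {
    digits[k] <- x %% 4
    x <- x %/% 4
  }
  paste0("TGT", paste(.codon_digits[digits + 1], collapse = ""), "TTT")
}

# Repertoire of length(counts) distinct clonotypes with the given UMI
# counts. Gene calls recycle over the vectors supplied.
make_rep <- function(counts, sample_id = "toy", group = "other",
                     subset = "other", v = "TRBV4", j = "TRBJ1-1",
                     d = "TRBD1", offset = 0L) {
  n <- length(counts)
  cl <- data.frame(
    cdr3_nt = vapply(seq_len(n) + offset, toy_junction, character(1)),
    v_gene = rep_len(v, n),
    d_gene = rep_len(d, n),
    j_gene = rep_len(j, n),
    count = counts,
    stringsAsFactors = FALSE
  )
  repertoire(cl, sample_id = sample_id, group = group, subset = subset)
}

# Random small repertoire for property tests (distinct clonotypes,
# counts >= 1). Call under a fixed seed.
random_rep <- function(n_max = 30L, count_max = 50L, sample_id = "rand") {
  n <- sample.int(n_max, 1)
  idx <- sample.int(4^4, n)  # distinct junction indices
  cl <- data.frame(
    cdr3_nt = vapply(idx, toy_junction, character(1)),
    v_gene = sample(c("TRBV4", "TRBV31", "TRBV12-2"), n, replace = TRUE),
    d_gene = "",
    j_gene = sample(c("TRBJ1-1", "TRBJ1-4"), n, replace = TRUE),
    count = sample.int(count_max, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  repertoire(cl, sample_id = sample_id)
}

# Independent brute-force oracles (straight transcription of the
# definitions; no shared code with the package internals).
oracle_shannon <- function(counts) {
  p <- counts / sum(counts)
  -sum(p * log(p))
}
oracle_simpson_D <- function(counts) {
  p <- counts / sum(counts)
  sum(p * p)
}
oracle_d50 <- function(counts) {
  s <- sort(counts, decreasing = TRUE)
  cum <- 0
  for (k in seq_along(s)) {
    cum <- cum + s[k]
    if (cum / sum(s) >= 0.5) return(100 * k / length(s))
  }
}
oracle_chao1 <- function(counts) {
  S <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) S + f1^2 / (2 * f2) else S + f1 * (f1 - 1) / 2
}
oracle_top100 <- function(counts) {
  s <- sort(counts, decreasing = TRUE)
  100 * sum(s[seq_len(min(100, length(s)))]) / sum(s)
}
oracle_hill <- function(counts, q) {
  p <- counts / sum(counts)
  if (q == 1) exp(-sum(p * log(p))) else sum(p^q)^(1 / (1 - q))
}
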