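# Productive clonotype rows with CDR3 amino-acid sequences and weights.
.aa_rows <- function(rep, weighting) {
  cl <- rep$clonotypes[rep$clonotypes$productive, , drop = FALSE]
  if (!nrow(cl)) stop("no productive clonotypes: amino-acid statistic undefined")
  w <- if (weighting == "total") cl$count else rep(1, nrow(cl))
  list(aa = cl$cdr3_aa, w = w)
}

# Residue count matrix (20 x n sequences).
.residue_counts <- function(aa) {
  vapply(strsplit(aa, ""), function(ch) {
    tabulate(match(ch, AA_ALPHABET), nbins = 20L)
  }, integer(20L))
}

#' CDR3 amino-acid composition
#'
#' Pooled residue frequencies over all productive CDR3 amino-acid
#' sequences, UMI-weighted (`total`) or per-clonotype (`unique`).
#'
#' @param rep a `tcr_repertoire`
#' @param weighting "total" or "unique"
#' @return named 20-vector over the standard amino acids, summing to 1
#' @export
aa_composition <- function(rep, weighting = c("total", "unique")) {
  weighting <- match.arg(weighting)
  rows <- .aa_rows(rep, weighting)
  counts <- .residue_counts(rows$aa) %*% rows$w
  freq <- as.numeric(counts) / sum(counts)
  setNames(freq, AA_ALPHABET)
}

#' Bhattacharyya distance between two composition vectors
#'
#' BD = -ln sum_a sqrt(p_a q_a). Zero iff the distributions are equal;
#' +Inf when the supports are disjoint (Bhattacharyya coefficient 0). Not
#' a metric (no triangle inequality), but symmetric and nonnegative.
#'
#' @param p,q nonnegative vectors of equal length, each summing to 1
#'   within 1e-6
#' @return nonnegative real, possibly Inf
#' @export
bhattacharyya_distance <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop("composition vectors must each sum to 1 (tolerance 1e-6)")
  }
  bc <- sum(sqrt(p * q))
  if (bc <= 0) return(Inf)
  max(0, -log(min(bc, 1)))
}

#' Hydrophobic doublet index
#'
#' Fraction (UMI-weighted by default) of productive CDR3s of the given
#' length class whose residues at 1-based positions 6 and 7 form a
#' hydrophobic doublet. Positions are counted from the conserved cysteine;
#' the default length class is 13, the canonical CDR3-beta spectratype
#' mode used for positional self-reactivity analyses. The doublet set
#' defaults to all pairs of strongly hydrophobic residues
#' (A, C, F, I, L, M, V, W, Y) and is configurable because the
#' self-reactivity literature uses curated promoting-doublet lists.
#'
#' @param rep a `tcr_repertoire`
#' @param length_class CDR3 amino-acid length to restrict to (default 13)
#' @param doublet_set character vector of 2-letter residue pairs counted
#'   as hydrophobic
#' @param weighting "total" or "unique"
#' @return fraction in \[0, 1\]
#' @export
hydrophobic_index <- function(rep, length_class = 13L,
                              doublet_set = hydrophobic_doublets(),
                              weighting = c("total", "unique")) {
  weighting <- match.arg(weighting)
  rows <- .aa_rows(rep, weighting)
  sel <- nchar(rows$aa) == length_class
  if (!any(sel)) {
    stop("no productive clonotype of CDR3 length ", length_class,
         " in sample ", rep$sample_id)
  }
  aa <- rows$aa[sel]
  w <- rows$w[sel]
  doublet <- paste0(substr(aa, 6, 6), substr(aa, 7, 7))
  sum(w[doublet %in% doublet_set]) / sum(w)
}

#' Default hydrophobic doublet set
#'
#' All ordered pairs of strongly hydrophobic residues.
#'
#' @param residues residue class (default A, C, F, I, L, M, V, W, Y)
#' @return character vector of 2-letter pairs
#' @export
hydrophobic_doublets <- function(residues = HYDROPHOBIC_RESIDUES) {
  as.vector(outer(residues, residues, paste0))
}

#' Cysteine index
#'
#' Fraction (UMI-weighted by default) of productive CDR3s containing a
#' cysteine within `window` positions of the CDR3 apex (midpoint),
#' excluding the invariant cysteine at position 1. Anchoring at the
#' midpoint reflects the apex-centered view of self-reactive CDR3 loops;
#' `anchor` also accepts "start" or "end".
#'
#' @param rep a `tcr_repertoire`
#' @param window half-width of the search window in residues (default 2)
#' @param anchor "midpoint", "start" or "end"
#' @param weighting "total" or "unique"
#' @return fraction in \[0, 1\]
#' @export
cysteine_index <- function(rep, window = 2L,
                           anchor = c("midpoint", "start", "end"),
                           weighting = c("total", "unique")) {
  anchor <- match.arg(anchor)
  weighting <- match.arg(weighting)
  rows <- .aa_rows(rep, weighting)
  has_c <- vapply(seq_along(rows$aa), function(i) {
    aa <- rows$aa[i]
    n <- nchar(aa)
    center <- switch(anchor,
      midpoint = (n + 1) / 2,
      start = 1,
      end = n)
    lo <- max(2L, ceiling(center - window))  # skip invariant position-1 C
    hi <- min(n, floor(center + window))
    if (lo > hi) return(FALSE)
    grepl("C", substr(aa, lo, hi), fixed = TRUE)
  }, logical(1))
  sum(rows$w[has_c]) / sum(rows$w)
}

#' Positional amino-acid composition
#'
#' Residue frequency vector at one 1-based CDR3 position among productive
#' clonotypes of a fixed length class.
#'
#' @param rep a `tcr_repertoire`
#' @param length_class CDR3 amino-acid length (default 13)
#' @param position 1-based position, counted from the conserved cysteine
#' @param weighting "total" or "unique"
#' @return named 20-vector summing to 1
#' @export
positional_composition <- function(rep, length_class = 13L, position = 6L,
                                   weighting = c("total", "unique")) {
  weighting <- match.arg(weighting)
  if (position < 1 || position > length_class) {
    stop("position must lie in 1..length_class")
  }
  rows <- .aa_rows(rep, weighting)
  sel <- nchar(rows$aa) == length_class
  if (!any(sel)) {
    stop("no productive clonotype of CDR3 length ", length_class)
  }
  res <- substr(rows$aa[sel], position, position)
  w <- rows$w[sel]
  freq <- tapply(w, factor(res, levels = AA_ALPHABET), sum)
  freq[is.na(freq)] <- 0
  setNames(as.numeric(freq) / sum(w), AA_ALPHABET)
}

#' Per-sample amino-acid feature profile
#'
#' @param rep a `tcr_repertoire`
#' @param length_class length class for positional analyses
#' @param weighting "total" or "unique"
#' @return list with `composition`, `hydrophobic_index`, `cysteine_index`
#'   (positional vectors are computed only when the length class is
#'   represented)
#' @export
aa_profile <- function(rep, length_class = 13L,
                       weighting = c("total", "unique")) {
  weighting <- match.arg(weighting)
  has_class <- any(nchar(rep$clonotypes$cdr3_aa[rep$clonotypes$productive]) ==
                     length_class)
  list(
    sample_id = rep$sample_id,
    composition = aa_composition(rep, weighting),
    hydrophobic_index = if (has_class) {
      hydrophobic_index(rep, length_class, weighting = weighting)
    } else NA_real_,
    cysteine_index = cysteine_index(rep, weighting = weighting),
    positional = if (has_class) {
      list(p6 = positional_composition(rep, length_class, 6L, weighting),
           p7 = positional_composition(rep, length_class, 7L, weighting))
    } else NULL,
    weighting = weighting
  )
}
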