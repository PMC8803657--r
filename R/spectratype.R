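#' CDR3 length distribution (spectratype)
#'
#' Exact-binned frequency of CDR3 lengths, in nucleotides by default (the
#' UMI-weighted `total` form or per-clonotype `unique` form). The
#' amino-acid unit restricts to productive clonotypes and uses residue
#' counts.
#'
#' @param rep a `tcr_repertoire`
#' @param weighting "total" or "unique"
#' @param unit "nt" or "aa"
#' @return named numeric vector frequency-per-length summing to 1, class
#'   `spectratype_hist`, names are lengths sorted ascending
#' @export
length_distribution <- function(rep, weighting = c("total", "unique"),
                                unit = c("nt", "aa")) {
  weighting <- match.arg(weighting)
  unit <- match.arg(unit)
  cl <- rep$clonotypes
  if (unit == "aa") cl <- cl[cl$productive, , drop = FALSE]
  if (!nrow(cl)) stop("empty repertoire: length distribution undefined")
  len <- if (unit == "nt") nchar(cl$cdr3_nt) else nchar(cl$cdr3_aa)
  w <- if (weighting == "total") cl$count else rep(1, nrow(cl))
  f <- tapply(w, len, sum) / sum(w)
  f <- f[order(as.integer(names(f)))]
  structure(as.numeric(f), names = names(f), weighting = weighting,
            unit = unit, class = "spectratype_hist")
}

#' Spectratype complexity score
#'
#' Number of length bins whose frequency reaches `threshold` — the
#' peak-count convention of spectratyping: how many distinct length peaks
#' the profile supports.
#'
#' @param hist a normalized length histogram ([length_distribution()])
#' @param threshold minimum frequency for a bin to count, in (0, 1)
#'   (default 0.01)
#' @return integer number of qualifying bins
#' @export
complexity_score <- function(hist, threshold = 0.01) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (abs(sum(hist) - 1) > 1e-6) stop("histogram must be normalized")
  sum(as.numeric(hist) >= threshold)
}

#' Skewness of the CDR3 length distribution
#'
#' Third standardized moment of the frequency-weighted length
#' distribution, sum f_L ((L - mu) / sigma)^3, using population (not
#' sample-corrected) moments: the histogram is the full repertoire, not a
#' sample of lengths. Degenerate (single-length) distributions return 0
#' with attribute `degenerate`.
#'
#' @param x a `tcr_repertoire` or a `spectratype_hist`
#' @param weighting "total" or "unique" (when `x` is a repertoire)
#' @param unit "nt" or "aa" (when `x` is a repertoire)
#' @return numeric skewness
#' @export
length_skewness <- function(x, weighting = c("total", "unique"),
                            unit = c("nt", "aa")) {
  h <- if (inherits(x, "spectratype_hist")) x else {
    length_distribution(x, match.arg(weighting), match.arg(unit))
  }
  L <- as.numeric(names(h))
  f <- as.numeric(h)
  mu <- sum(f * L)
  v <- sum(f * (L - mu)^2)
  if (v <= 0) return(structure(0, degenerate = TRUE))
  sum(f * ((L - mu) / sqrt(v))^3)
}

#' Spectratype profile summary
#'
#' @param rep a `tcr_repertoire`
#' @param weighting "total" or "unique"
#' @param threshold complexity-score frequency threshold
#' @return list with `histogram`, `complexity`, `skewness`, `weighting`
#' @export
spectratype_profile <- function(rep, weighting = c("total", "unique"),
                                threshold = 0.01) {
  weighting <- match.arg(weighting)
  h <- length_distribution(rep, weighting)
  list(sample_id = rep$sample_id, histogram = h,
       complexity = complexity_score(h, threshold),
       skewness = as.numeric(length_skewness(h)),
       weighting = weighting, threshold = threshold)
}
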