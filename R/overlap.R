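# Collapse a repertoire to key -> frequency under a species definition
# (keys may merge, e.g. aa mode; frequencies are summed).
.key_freqs <- function(rep, key_mode) {
  if (!richness(rep)) stop("empty repertoire: overlap undefined")
  key <- clonotype_key(rep, key_mode)
  f <- tapply(rep$clonotypes$count, key, sum) / rep$total_count
  setNames(as.numeric(f), names(f))
}

#' Overlap coefficient between two repertoires
#'
#' overlap(X, Y) = |X intersect Y| / min(|X|, |Y|) on clonotype key sets.
#' The default species is the CDR3 nucleotide sequence alone.
#'
#' @param x,y `tcr_repertoire` objects
#' @param key_mode clonotype species; see [clonotype_key()]
#' @return value in \[0, 1\]
#' @export
overlap_coefficient <- function(x, y, key_mode = "nt") {
  fx <- .key_freqs(x, key_mode)
  fy <- .key_freqs(y, key_mode)
  length(intersect(names(fx), names(fy))) / min(length(fx), length(fy))
}

#' F2 repertoire similarity
#'
#' Summed geometric-mean frequency of shared clonotypes,
#' F2 = sum over shared i of sqrt(f_x(i) f_y(i)) (VDJTOOLS definition):
#' the share of the two repertoires occupied by common clonotypes. 1 for
#' identical repertoires, 0 for disjoint ones.
#'
#' @inheritParams overlap_coefficient
#' @return value in \[0, 1\]
#' @export
f2_metric <- function(x, y, key_mode = "nt_vj") {
  fx <- .key_freqs(x, key_mode)
  fy <- .key_freqs(y, key_mode)
  shared <- intersect(names(fx), names(fy))
  if (!length(shared)) return(0)
  sum(sqrt(fx[shared] * fy[shared]))
}

#' R repertoire similarity
#'
#' Pearson correlation of log10 frequencies of shared clonotypes
#' (VDJTOOLS convention): the similarity of repertoire organization.
#' Undefined (NA with attribute `undefined`) below 2 shared clonotypes or
#' when either side has zero variance.
#'
#' @inheritParams overlap_coefficient
#' @return correlation in \[-1, 1\], or NA flagged undefined
#' @export
r_metric <- function(x, y, key_mode = "nt_vj") {
  fx <- .key_freqs(x, key_mode)
  fy <- .key_freqs(y, key_mode)
  shared <- intersect(names(fx), names(fy))
  if (length(shared) < 2) {
    return(structure(NA_real_, undefined = "fewer than 2 shared clonotypes"))
  }
  lx <- log10(fx[shared])
  ly <- log10(fy[shared])
  if (sd(lx) == 0 || sd(ly) == 0) {
    return(structure(NA_real_, undefined = "zero variance in log frequencies"))
  }
  unname(cor(lx, ly))
}

#' D relative overlap diversity
#'
#' D = n_shared / (richness_x * richness_y) (VDJTOOLS definition): a
#' frequency-blind, size-normalized count of shared clonotypes.
#'
#' @inheritParams overlap_coefficient
#' @return nonnegative real (1 only for identical single-clonotype sets)
#' @export
d_metric <- function(x, y, key_mode = "nt_vj") {
  fx <- .key_freqs(x, key_mode)
  fy <- .key_freqs(y, key_mode)
  length(intersect(names(fx), names(fy))) / (length(fx) * length(fy))
}

#' All pairwise overlap statistics for two repertoires
#'
#' @inheritParams overlap_coefficient
#' @param key_mode_oc species for the overlap coefficient (default "nt",
#'   the explicit set-coefficient convention)
#' @param key_mode_frd species for F2/R/D (default "nt_vj", the strict
#'   VDJTOOLS convention)
#' @return one-row data.frame (sample_x, sample_y, n_shared,
#'   overlap_coefficient, F2, R, D, key_mode_oc, key_mode_frd)
#' @export
repertoire_overlap <- function(x, y, key_mode_oc = "nt",
                               key_mode_frd = "nt_vj") {
  fx <- .key_freqs(x, key_mode_frd)
  fy <- .key_freqs(y, key_mode_frd)
  data.frame(
    sample_x = x$sample_id, sample_y = y$sample_id,
    n_shared = length(intersect(names(fx), names(fy))),
    overlap_coefficient = overlap_coefficient(x, y, key_mode_oc),
    F2 = f2_metric(x, y, key_mode_frd),
    R = as.numeric(r_metric(x, y, key_mode_frd)),
    D = d_metric(x, y, key_mode_frd),
    key_mode_oc = key_mode_oc, key_mode_frd = key_mode_frd,
    stringsAsFactors = FALSE
  )
}

#' Pairwise distance matrix over repertoires
#'
#' distance = 1 - overlap_coefficient (default) or 1 - F2; symmetric with a
#' zero diagonal, suitable for heatmap display.
#'
#' @param reps list of >= 2 `tcr_repertoire` objects
#' @param metric "overlap" or "F2"
#' @param key_mode clonotype species (default "nt" for overlap, "nt_vj"
#'   for F2 when left NULL)
#' @return symmetric numeric matrix with sample ids as dimnames
#' @export
distance_matrix <- function(reps, metric = c("overlap", "F2"),
                            key_mode = NULL) {
  metric <- match.arg(metric)
  if (length(reps) < 2) stop("need >= 2 repertoires")
  if (is.null(key_mode)) key_mode <- if (metric == "overlap") "nt" else "nt_vj"
  ids <- vapply(reps, function(r) r$sample_id, character(1))
  n <- length(reps)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  fn <- if (metric == "overlap") overlap_coefficient else f2_metric
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- 1 - fn(reps[[i]], reps[[j]], key_mode)
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  attr(m, "metric") <- metric
  attr(m, "key_mode") <- key_mode
  m
}
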