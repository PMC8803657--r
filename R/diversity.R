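#' Shannon-Wiener diversity index
#'
#' H = -sum p_i ln p_i over clonotype frequencies, in nats. A repertoire
#' holding a single clonotype has H = 0.
#'
#' @param x a `tcr_repertoire` or a vector of positive counts
#' @return nonnegative numeric
#' @export
#' @examples
#' shannon(c(1, 1, 1, 1))  # log(4)
shannon <- function(x) {
  cnt <- .counts_of(x)
  p <- cnt / sum(cnt)
  -sum(p * log(p))
}

#' Simpson dominance and diversity
#'
#' Returns both conventions explicitly, since "Simpson index" is used for
#' either in the literature: `dominance` D = sum p_i^2 (probability two
#' sequences drawn at random are the same clonotype; higher = more clonal)
#' and `diversity` 1 - D.
#'
#' @inheritParams shannon
#' @return named numeric vector `c(dominance =, diversity =)`
#' @export
simpson <- function(x) {
  cnt <- .counts_of(x)
  p <- cnt / sum(cnt)
  D <- sum(p^2)
  c(dominance = D, diversity = 1 - D)
}

#' D50 clonal diversity index
#'
#' Percentage of top-ranked unique clonotypes needed to account for half of
#' all sequences: rank clonotypes by descending count, take the smallest k
#' with cumulative frequency >= 0.5, report 100 * k / richness. Low values
#' indicate clonal expansion.
#'
#' @inheritParams shannon
#' @return percent in (0, 100]
#' @export
d50 <- function(x) {
  cnt <- sort(.counts_of(x), decreasing = TRUE)
  k <- which(cumsum(cnt) / sum(cnt) >= 0.5)[1]
  100 * k / length(cnt)
}

#' Chao1 richness estimator
#'
#' Classic form S_obs + f1^2 / (2 f2) when doubletons exist; the
#' bias-corrected form S_obs + f1 (f1 - 1) / (2 (f2 + 1)) when f2 = 0, or
#' always when `bias_correct = "always"`. f1 and f2 are the numbers of
#' clonotypes seen with UMI count exactly 1 and 2.
#'
#' @inheritParams shannon
#' @param bias_correct "auto" (classic unless f2 = 0) or "always"
#' @return estimated richness, always >= observed richness
#' @export
chao1 <- function(x, bias_correct = c("auto", "always")) {
  bias_correct <- match.arg(bias_correct)
  cnt <- .counts_of(x)
  S <- length(cnt)
  f1 <- sum(cnt == 1)
  f2 <- sum(cnt == 2)
  if (bias_correct == "always" || f2 == 0) {
    S + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    S + f1^2 / (2 * f2)
  }
}

#' Top100 cumulative frequency
#'
#' Percentage of all sequences occupied by the 100 most abundant
#' clonotypes; 100 when the repertoire holds at most 100 clonotypes.
#'
#' @inheritParams shannon
#' @param n_top number of top clonotypes to pool (default 100)
#' @return percent in (0, 100]
#' @export
top100 <- function(x, n_top = 100L) {
  cnt <- sort(.counts_of(x), decreasing = TRUE)
  100 * sum(head(cnt, n_top)) / sum(cnt)
}

#' Hill number (true diversity) of order q
#'
#' qD = (sum p_i^q)^(1/(1-q)); q = 0 gives richness, q = 1 is the limit
#' exp(H) (exponential Shannon), q = 2 the inverse Simpson index.
#'
#' @inheritParams shannon
#' @param q nonnegative diversity order(s)
#' @return numeric vector of qD values, one per q
#' @export
hill_number <- function(x, q) {
  if (any(q < 0)) stop("Hill order q must be nonnegative")
  cnt <- .counts_of(x)
  p <- cnt / sum(cnt)
  vapply(q, function(qi) {
    if (abs(qi - 1) < 1e-12) exp(-sum(p * log(p)))
    else sum(p^qi)^(1 / (1 - qi))
  }, numeric(1))
}

#' Hill diversity curve
#'
#' Evaluates qD over a grid of orders (default 0 to 8 in steps of 0.25,
#' matching typical true-diversity profile plots).
#'
#' @inheritParams shannon
#' @param q_grid nonnegative grid of orders
#' @return data.frame with columns `q`, `qD`
#' @export
hill_curve <- function(x, q_grid = seq(0, 8, by = 0.25)) {
  data.frame(q = q_grid, qD = hill_number(x, q_grid))
}

#' Rank-abundance profile
#'
#' Clonotype frequencies sorted descending with 1-based ranks.
#'
#' @inheritParams shannon
#' @return data.frame with columns `rank`, `frequency` (sums to 1)
#' @export
rank_abundance <- function(x) {
  cnt <- sort(.counts_of(x), decreasing = TRUE)
  data.frame(rank = seq_along(cnt), frequency = cnt / sum(cnt))
}

#' Cumulative unique-versus-total clonotype curve
#'
#' With clonotypes sorted by descending count, plots the cumulative
#' fraction of sequences accounted for against the fraction of unique
#' clonotypes used; steeply rising curves indicate clonal expansion. The
#' curve is non-decreasing and ends at (1, 1).
#'
#' @inheritParams shannon
#' @return data.frame with columns `fraction_unique`, `cumulative_frequency`
#' @export
cumulative_clonotype_curve <- function(x) {
  cnt <- sort(.counts_of(x), decreasing = TRUE)
  data.frame(
    fraction_unique = seq_along(cnt) / length(cnt),
    cumulative_frequency = cumsum(cnt) / sum(cnt)
  )
}

#' Full per-sample diversity profile
#'
#' Bundles richness, Shannon, both Simpson forms, D50, Chao1, Top100 and
#' the Hill curve for one repertoire.
#'
#' @inheritParams shannon
#' @param q_grid grid of Hill orders
#' @return object of class `diversity_profile` (a list); its `summary_row`
#'   element is a one-row data.frame for table assembly
#' @export
diversity_profile <- function(x, q_grid = seq(0, 8, by = 0.25)) {
  cnt <- .counts_of(x)
  sim <- simpson(cnt)
  prof <- list(
    sample_id = if (inherits(x, "tcr_repertoire")) x$sample_id else NA_character_,
    richness = length(cnt),
    shannon = shannon(cnt),
    simpson_dominance = unname(sim["dominance"]),
    simpson_diversity = unname(sim["diversity"]),
    d50 = d50(cnt),
    chao1 = chao1(cnt),
    top100 = top100(cnt),
    total_count = sum(cnt),
    hill = hill_curve(cnt, q_grid),
    rank_abundance = rank_abundance(cnt)
  )
  prof$summary_row <- data.frame(
    sample_id = prof$sample_id, richness = prof$richness,
    total_count = prof$total_count, shannon = prof$shannon,
    simpson_dominance = prof$simpson_dominance,
    simpson_diversity = prof$simpson_diversity,
    d50 = prof$d50, chao1 = prof$chao1, top100 = prof$top100,
    stringsAsFactors = FALSE
  )
  structure(prof, class = "diversity_profile")
}

#' @export
print.diversity_profile <- function(x, ...) {
  cat(sprintf(
    paste0("<diversity_profile> %s: richness %d, Shannon %.4f, ",
           "Simpson 1-D %.4f, D50 %.1f%%, Chao1 %.1f, Top100 %.1f%%\n"),
    x$sample_id, x$richness, x$shannon, x$simpson_diversity, x$d50,
    x$chao1, x$top100))
  invisible(x)
}

# Registry of scalar index functions addressable by name (rarefaction,
# feature assembly, CLI).
.index_registry <- function() {
  list(
    richness = function(x) length(.counts_of(x)),
    shannon = shannon,
    simpson = function(x) unname(simpson(x)["diversity"]),
    simpson_dominance = function(x) unname(simpson(x)["dominance"]),
    d50 = d50,
    chao1 = chao1,
    top100 = top100
  )
}

#' Look up a diversity index function by name
#' @param name one of "richness", "shannon", "simpson" (1-D),
#'   "simpson_dominance", "d50", "chao1", "top100"
#' @return a function of a repertoire or count vector
#' @export
index_function <- function(name) {
  reg <- .index_registry()
  if (!name %in% names(reg)) {
    stop("unknown index '", name, "'; valid: ",
         paste(names(reg), collapse = ", "))
  }
  reg[[name]]
}
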