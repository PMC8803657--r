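#' Rarefaction plan
#'
#' Depths and replicate count for UMI-depth normalization. Defaults follow
#' the standard ladder of 4,000 / 6,000 / 8,000 / 10,000 / 12,000 UMIs per
#' sample.
#'
#' @param depths positive integer depths, sorted ascending
#' @param replicates replicate draws per depth (>= 1)
#' @param seed base RNG seed
#' @return object of class `rarefaction_plan`
#' @export
rarefaction_plan <- function(depths = c(4000L, 6000L, 8000L, 10000L, 12000L),
                             replicates = 10L, seed = 1L) {
  depths <- as.integer(depths)
  if (any(depths < 1)) stop("depths must be >= 1")
  if (is.unsorted(depths)) stop("depths must be sorted ascending")
  replicates <- as.integer(replicates)
  if (replicates < 1) stop("replicates must be >= 1")
  structure(list(depths = depths, replicates = replicates,
                 seed = as.integer(seed)),
            class = "rarefaction_plan")
}

#' Subsample a repertoire to a fixed UMI depth
#'
#' Draws exactly `depth` UMIs without replacement from the multiset of
#' observed molecules (multivariate hypergeometric), so no clonotype's
#' subsampled count can exceed its original count and depth = total
#' reproduces the input. Clonotypes reduced to zero are removed.
#' Deterministic for a given seed.
#'
#' @param rep a `tcr_repertoire`
#' @param depth target UMI total, <= `rep$total_count`
#' @param seed RNG seed (NULL uses the current RNG stream)
#' @return a `tcr_repertoire` with total_count == depth
#' @export
subsample <- function(rep, depth, seed = NULL) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  depth <- as.integer(depth)
  if (depth < 1) stop("depth must be >= 1")
  if (depth > rep$total_count) {
    stop("depth ", depth, " exceeds total UMI count ", rep$total_count,
         " of sample ", rep$sample_id)
  }
  counts <- rep$clonotypes$count
  if (depth == rep$total_count) return(rep)
  new_counts <- with_seed(seed, {
    out <- integer(length(counts))
    remaining_total <- sum(counts)
    remaining_draw <- depth
    for (i in seq_along(counts)) {
      if (remaining_draw == 0L) break
      # sequential conditional draw of the multivariate hypergeometric
      x <- rhyper(1L, counts[i], remaining_total - counts[i], remaining_draw)
      out[i] <- x
      remaining_draw <- remaining_draw - x
      remaining_total <- remaining_total - counts[i]
    }
    out
  })
  keep <- new_counts > 0L
  cl <- rep$clonotypes[keep, , drop = FALSE]
  cl$count <- as.integer(new_counts[keep])
  repertoire(cl, sample_id = rep$sample_id, group = rep$group,
             subset = rep$subset, productive_only = FALSE, validate = FALSE)
}

#' Rarefy a diversity index over a depth ladder
#'
#' Evaluates a named index on repeated random subsamples at each planned
#' depth. Depths exceeding the sample's total are skipped with a warning
#' (never upsampled). Fully reproducible from the plan's seed.
#'
#' @param rep a `tcr_repertoire`
#' @param plan a [rarefaction_plan()]
#' @param index index name understood by [index_function()]
#' @return data.frame (sample_id, depth, replicate, index, value); the
#'   attribute `"means"` holds per-depth replicate means
#' @export
rarefy_index <- function(rep, plan = rarefaction_plan(), index = "shannon") {
  fn <- index_function(index)
  depths <- plan$depths
  usable <- depths <= rep$total_count
  if (!all(usable)) {
    warning("sample ", rep$sample_id, ": skipping depth(s) ",
            paste(depths[!usable], collapse = ", "),
            " above total count ", rep$total_count, call. = FALSE)
    depths <- depths[usable]
  }
  rows <- vector("list", length(depths) * plan$replicates)
  k <- 0L
  for (di in seq_along(depths)) {
    for (r in seq_len(plan$replicates)) {
      sub <- subsample(rep, depths[di],
                       seed = derive_seed(plan$seed, di * 100000L + r))
      k <- k + 1L
      rows[[k]] <- data.frame(
        sample_id = rep$sample_id, depth = depths[di], replicate = r,
        index = index, value = fn(sub), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  if (is.null(out)) {
    out <- data.frame(sample_id = character(), depth = integer(),
                      replicate = integer(), index = character(),
                      value = numeric(), stringsAsFactors = FALSE)
  }
  means <- if (nrow(out)) {
    aggregate(value ~ depth, data = out, FUN = mean)
  } else data.frame(depth = integer(), value = numeric())
  attr(out, "means") <- means
  out
}
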