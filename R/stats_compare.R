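#' Assemble a per-sample feature matrix
#'
#' Builds the matrix feeding PCA and group tests. Default features are the
#' four summary variables: Shannon, Simpson diversity (1-D), the number of
#' total sequences (UMIs) and the number of unique sequences. Feature
#' modes `v_usage`, `vj_usage`, `vdj_usage` expand into one column per
#' gene (or tuple) observed in any sample, UMI-weighted.
#'
#' @param reps list of >= 3 `tcr_repertoire` objects
#' @param features character vector of scalar index names (see
#'   [index_function()]; aliases `total_sequences`, `unique_sequences`)
#'   or one of the usage modes
#' @param scaling "zscore" (default) or "none"
#' @param log_counts log10-transform the two sequence-count features
#'   before scaling
#' @return numeric matrix, samples x features, with attributes `groups`,
#'   `subsets`, `scaling`; zero-variance columns are dropped with a warning
#' @export
assemble_features <- function(reps,
                              features = c("shannon", "simpson",
                                           "total_sequences",
                                           "unique_sequences"),
                              scaling = c("zscore", "none"),
                              log_counts = FALSE) {
  scaling <- match.arg(scaling)
  if (length(reps) < 3) stop("need >= 3 samples to assemble features")
  ids <- vapply(reps, function(r) r$sample_id, character(1))
  usage_modes <- c(v_usage = "V", vj_usage = "VJ", vdj_usage = "VDJ")
  if (length(features) == 1 && features %in% names(usage_modes)) {
    axis <- usage_modes[[features]]
    tabs <- lapply(reps, usage, axis = axis, weighting = "total")
    genes <- sort(unique(unlist(lapply(tabs, names))))
    m <- t(vapply(tabs, function(tab) {
      v <- setNames(numeric(length(genes)), genes)
      v[names(tab)] <- as.numeric(tab)
      v
    }, numeric(length(genes))))
  } else {
    cols <- lapply(features, function(f) {
      vapply(reps, function(r) {
        switch(f,
          total_sequences = {
            v <- as.numeric(r$total_count)
            if (log_counts) log10(v) else v
          },
          unique_sequences = {
            v <- as.numeric(richness(r))
            if (log_counts) log10(v) else v
          },
          index_function(f)(r))
      }, numeric(1))
    })
    m <- do.call(cbind, cols)
    colnames(m) <- features
  }
  rownames(m) <- ids
  if (anyNA(m)) {
    bad <- rownames(m)[apply(m, 1, anyNA)]
    warning("dropping sample(s) with missing features: ",
            paste(bad, collapse = ", "), call. = FALSE)
    keep <- !rownames(m) %in% bad
    m <- m[keep, , drop = FALSE]
    reps <- reps[keep]
  }
  if (scaling == "zscore") {
    sds <- apply(m, 2, sd)
    if (any(sds == 0)) {
      warning("dropping zero-variance feature(s): ",
              paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
      m <- m[, sds > 0, drop = FALSE]
    }
    m <- scale(m)
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
  }
  attr(m, "groups") <- vapply(reps, function(r) r$group, character(1))
  attr(m, "subsets") <- vapply(reps, function(r) r$subset, character(1))
  attr(m, "scaling") <- scaling
  m
}

#' PCA of a feature matrix
#'
#' Principal component analysis with a deterministic sign convention: the
#' largest-magnitude entry of each loading vector is forced positive, so
#' repeated runs are bit-comparable. Rank-deficient inputs yield fewer
#' components with a warning.
#'
#' @param fm matrix from [assemble_features()]
#' @param n_components number of components to keep
#' @return list with `scores` (samples x components), `loadings`
#'   (features x components), `explained_variance` (fractions), `groups`
#' @export
pca_segregation <- function(fm, n_components = 2L) {
  n_max <- min(nrow(fm) - 1L, ncol(fm))
  if (n_components > n_max) {
    stop("n_components must be <= min(#samples - 1, #features) = ", n_max)
  }
  pc <- prcomp(fm, center = attr(fm, "scaling") != "zscore", scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-9)
  if (rank < n_components) {
    warning("matrix rank ", rank, " < requested components; returning ",
            rank, call. = FALSE)
    n_components <- rank
  }
  keep <- seq_len(n_components)
  rot <- pc$rotation[, keep, drop = FALSE]
  sco <- pc$x[, keep, drop = FALSE]
  for (k in keep) {
    i <- which.max(abs(rot[, k]))
    if (rot[i, k] < 0) {
      rot[, k] <- -rot[, k]
      sco[, k] <- -sco[, k]
    }
  }
  list(scores = sco, loadings = rot, explained_variance = ev[keep],
       groups = attr(fm, "groups"))
}

#' Two-group test on a scalar feature
#'
#' Two-sided Student's t-test or Wilcoxon rank-sum test. Fully tied data
#' (all values identical in both groups) return p = 1 with a degenerate
#' flag instead of erroring.
#'
#' @param values_a,values_b numeric vectors, >= 2 values each
#' @param method "t_test" or "wilcoxon"
#' @return list(statistic, p, degenerate)
#' @export
group_test <- function(values_a, values_b,
                       method = c("t_test", "wilcoxon")) {
  method <- match.arg(method)
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("need >= 2 values per group")
  }
  if (sd(values_a) == 0 && sd(values_b) == 0 &&
      mean(values_a) == mean(values_b)) {
    return(list(statistic = NA_real_, p = 1, degenerate = TRUE))
  }
  res <- if (method == "t_test") {
    t.test(values_a, values_b)
  } else {
    suppressWarnings(wilcox.test(values_a, values_b, exact = FALSE))
  }
  list(statistic = unname(res$statistic), p = res$p.value,
       degenerate = FALSE)
}

#' Adjust p-values across a test family
#'
#' "BH" and "bonferroni" delegate to [stats::p.adjust()]. "dunnett"
#' approximates Dunnett-style control of the family of t-tests through a
#' Monte-Carlo max-|t| reference: m independent t-variates with the given
#' degrees of freedom are drawn `reps` times, and each adjusted p-value is
#' the tail probability that the maximum absolute draw exceeds the
#' observed |t|.
#'
#' @param p raw p-values
#' @param method "BH", "bonferroni", "dunnett" or "none"
#' @param statistic observed t statistics (dunnett only)
#' @param df residual degrees of freedom (dunnett only)
#' @param reps Monte-Carlo replicates
#' @param seed RNG seed for the Monte-Carlo draw
#' @return adjusted p-values
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni", "dunnett",
                                         "none"),
                           statistic = NULL, df = NULL, reps = 20000L,
                           seed = 1L) {
  method <- match.arg(method)
  if (method %in% c("BH", "bonferroni", "none")) {
    return(p.adjust(p, method = if (method == "none") "none" else method))
  }
  if (is.null(statistic) || is.null(df)) {
    stop("dunnett adjustment needs t statistics and degrees of freedom")
  }
  m <- length(p)
  ok <- !is.na(statistic)
  adj <- p
  if (any(ok)) {
    maxt <- with_seed(seed, {
      draws <- matrix(abs(rt(reps * m, df = df)), nrow = reps)
      apply(draws, 1, max)
    })
    adj[ok] <- vapply(abs(statistic[ok]), function(t0) {
      mean(maxt >= t0)
    }, numeric(1))
  }
  pmin(adj, 1)
}
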