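#' V/D/J segment usage frequencies
#'
#' Frequency of each gene segment (or V-J / V-D-J combination) in a
#' repertoire. `weighting = "total"` weights clonotypes by UMI count (share
#' of total sequences); `"unique"` counts each clonotype once (share of
#' unique sequences). Clonotypes lacking a D call are pooled under
#' `"unassigned"` so frequencies always sum to 1.
#'
#' @param rep a `tcr_repertoire`
#' @param axis one of "V", "D", "J", "VJ", "VDJ"
#' @param weighting "total" (UMI-weighted) or "unique"
#' @return a `usage_table`: named numeric vector of frequencies summing to
#'   1, with attributes `axis`, `weighting` and `n` (the weight total)
#' @export
usage <- function(rep, axis = c("V", "D", "J", "VJ", "VDJ"),
                  weighting = c("total", "unique")) {
  axis <- match.arg(axis)
  weighting <- match.arg(weighting)
  cl <- rep$clonotypes
  if (!nrow(cl)) stop("empty repertoire: usage undefined")
  d <- ifelse(cl$d_gene == "", "unassigned", cl$d_gene)
  labels <- switch(axis,
    V = cl$v_gene,
    D = d,
    J = cl$j_gene,
    VJ = paste(cl$v_gene, cl$j_gene, sep = "|"),
    VDJ = paste(cl$v_gene, d, cl$j_gene, sep = "|")
  )
  w <- if (weighting == "total") cl$count else rep(1, nrow(cl))
  tot <- sum(w)
  freq <- tapply(w, labels, sum) / tot
  freq <- freq[order(names(freq))]
  structure(as.numeric(freq), names = names(freq), axis = axis,
            weighting = weighting, n = tot, class = "usage_table")
}

#' @export
print.usage_table <- function(x, ...) {
  cat(sprintf("<usage_table> axis=%s weighting=%s (n=%s)\n",
              attr(x, "axis"), attr(x, "weighting"),
              format(attr(x, "n"))))
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' V-J or V-D-J combination frequency matrix
#'
#' Joint frequency table over observed gene tuples; marginals of the VJ
#' table equal the corresponding single-axis usage tables.
#'
#' @inheritParams usage
#' @param axis "VJ" or "VDJ"
#' @return a `usage_table` keyed by `V|J` (or `V|D|J`) tuples
#' @export
combination_matrix <- function(rep, axis = c("VJ", "VDJ"),
                               weighting = c("total", "unique")) {
  axis <- match.arg(axis)
  usage(rep, axis = axis, weighting = match.arg(weighting))
}

#' Marginalize a combination usage table
#'
#' Sums a `VJ` or `VDJ` table over the tuple components not requested,
#' e.g. `usage_marginal(vj, "V")` reproduces the V usage table.
#'
#' @param tab a `usage_table` with a tuple axis
#' @param over the component(s) to keep: subset of the axis letters, in
#'   axis order (e.g. "V", "J", "VJ")
#' @return a `usage_table` on the reduced axis
#' @export
usage_marginal <- function(tab, over) {
  axis <- attr(tab, "axis")
  if (!axis %in% c("VJ", "VDJ")) stop("usage_marginal needs a tuple axis")
  parts <- strsplit(names(tab), "|", fixed = TRUE)
  letters_axis <- strsplit(axis, "")[[1]]
  keep <- match(strsplit(over, "")[[1]], letters_axis)
  if (anyNA(keep)) stop("'over' must be a subset of axis ", axis)
  key <- vapply(parts, function(p) paste(p[keep], collapse = "|"),
                character(1))
  freq <- tapply(as.numeric(tab), key, sum)
  freq <- freq[order(names(freq))]
  structure(as.numeric(freq), names = names(freq), axis = over,
            weighting = attr(tab, "weighting"), n = attr(tab, "n"),
            class = "usage_table")
}

#' Compare segment usage between two groups of samples
#'
#' One test per gene present in either group (a gene missing from a sample
#' enters as frequency 0). `t_test` and `wilcoxon` compare per-sample
#' frequencies across samples; `chi2` pools approximate counts
#' (frequency x weight total) and tests gene versus rest in a 2x2 table.
#' Degenerate cases (zero variance in both groups) are flagged, not
#' crashed: the p-value is 1 and `note` says "degenerate".
#'
#' @param group_a,group_b lists of `usage_table`s on the same axis/weighting
#' @param method "t_test", "wilcoxon" or "chi2"
#' @param p_adjust multiplicity correction across genes: "BH" (default),
#'   "bonferroni", "dunnett" (Monte-Carlo max-|t| reference; t_test only)
#'   or "none"
#' @param dunnett_reps Monte-Carlo replicates for the Dunnett reference
#' @param seed seed for the Dunnett Monte-Carlo draw
#' @return data.frame (gene, mean_a, mean_b, statistic, p, p_adjusted, note)
#' @export
compare_usage <- function(group_a, group_b,
                          method = c("t_test", "wilcoxon", "chi2"),
                          p_adjust = c("BH", "bonferroni", "dunnett", "none"),
                          dunnett_reps = 20000L, seed = 1L) {
  method <- match.arg(method)
  p_adjust <- match.arg(p_adjust)
  if (method != "chi2" && (length(group_a) < 2 || length(group_b) < 2)) {
    stop(method, " requires >= 2 samples per group")
  }
  genes <- sort(unique(c(unlist(lapply(group_a, names)),
                         unlist(lapply(group_b, names)))))
  mat <- function(group) {
    vapply(group, function(tab) {
      v <- setNames(numeric(length(genes)), genes)
      v[names(tab)] <- as.numeric(tab)
      v
    }, numeric(length(genes)))
  }
  A <- mat(group_a)
  B <- mat(group_b)
  if (length(genes) == 1L) {
    A <- matrix(A, nrow = 1, dimnames = list(genes, NULL))
    B <- matrix(B, nrow = 1, dimnames = list(genes, NULL))
  }
  res <- lapply(genes, function(g) {
    a <- A[g, ]
    b <- B[g, ]
    note <- ""
    if (method == "chi2") {
      na <- sum(vapply(group_a, function(t) attr(t, "n"), numeric(1)))
      nb <- sum(vapply(group_b, function(t) attr(t, "n"), numeric(1)))
      ka <- round(mean(a) * na)
      kb <- round(mean(b) * nb)
      tabm <- rbind(c(ka, na - ka), c(kb, nb - kb))
      if (any(rowSums(tabm) == 0) || any(colSums(tabm) == 0)) {
        stat <- NA_real_; p <- 1; note <- "degenerate"
      } else {
        ct <- suppressWarnings(chisq.test(tabm, correct = FALSE))
        stat <- unname(ct$statistic); p <- ct$p.value
      }
    } else if (sd(a) == 0 && sd(b) == 0) {
      stat <- NA_real_
      p <- if (mean(a) == mean(b)) 1 else NA_real_
      note <- "degenerate"
    } else if (method == "t_test") {
      tt <- t.test(a, b)
      stat <- unname(tt$statistic); p <- tt$p.value
    } else {
      wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
      stat <- unname(wt$statistic); p <- wt$p.value
    }
    data.frame(gene = g, mean_a = mean(a), mean_b = mean(b),
               statistic = stat, p = p, note = note,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- adjust_pvalues(out$p, method = p_adjust,
                                   statistic = out$statistic,
                                   df = length(group_a) + length(group_b) - 2,
                                   reps = dunnett_reps, seed = seed)
  out[, c("gene", "mean_a", "mean_b", "statistic", "p", "p_adjusted", "note")]
}
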