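#' Translate CDR3 nucleotide sequences
#'
#' Standard-genetic-code translation of in-frame A/C/G/T sequences.
#' Sequences whose length is not a multiple of 3 (or that contain other
#' characters) yield NA.
#'
#' @param nt character vector of nucleotide sequences
#' @return character vector of amino-acid sequences ('*' marks stop codons)
#' @export
#' @examples
#' translate_cdr3("TGTGCCAGCAGC")  # "CASS"
translate_cdr3 <- function(nt) {
  nt <- toupper(as.character(nt))
  aa <- rep(NA_character_, length(nt))
  ok <- !is.na(nt) & nchar(nt) > 0 & nchar(nt) %% 3 == 0 &
    !grepl("[^ACGT]", nt)
  if (any(ok)) {
    aa[ok] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(nt[ok]), no.init.codon = TRUE))
  }
  aa
}

#' Normalize a V/D/J segment gene name
#'
#' Strips allele suffixes (`*01`), converts dot family separators to the
#' IMGT dash form (`TRBV12.2` -> `TRBV12-2`), trims whitespace and
#' uppercases. Idempotent. Names that do not look like TR segment genes are
#' kept (post-transformation) with a warning rather than dropped.
#'
#' @param raw character vector of raw gene labels
#' @return character vector of normalized names ("" stays "")
#' @export
#' @examples
#' normalize_gene_name(c("TRBV12.2", "TRBJ1-1*01"))
normalize_gene_name <- function(raw) {
  x <- toupper(trimws(as.character(raw)))
  x[is.na(x)] <- ""
  nz <- x != ""
  x[nz] <- sub("\\*.*$", "", x[nz])
  x[nz] <- gsub("\\.", "-", x[nz])
  bad <- nz & !grepl("^TR[ABGD][VDJ]", x)
  if (any(bad)) {
    warning("unrecognized gene name(s) kept verbatim: ",
            paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  x
}

#' Clonotype keys for a repertoire
#'
#' The clonotype "species" definition used for merging and overlap:
#' `nt` (CDR3 nucleotide sequence only, the default species for the overlap
#' coefficient), `nt_vj` (nucleotide + V + J, the strict species used for
#' usage-aware analyses and the F2/R/D defaults), or `aa` (amino-acid
#' sequence).
#'
#' @param x a `tcr_repertoire` or a clonotype data.frame
#' @param key_mode one of "nt", "nt_vj", "aa"
#' @return character vector of keys, one per clonotype row
#' @export
clonotype_key <- function(x, key_mode = c("nt_vj", "nt", "aa")) {
  key_mode <- match.arg(key_mode)
  cl <- if (inherits(x, "tcr_repertoire")) x$clonotypes else x
  switch(key_mode,
    nt    = cl$cdr3_nt,
    nt_vj = paste(cl$cdr3_nt, cl$v_gene, cl$j_gene, sep = "|"),
    aa    = cl$cdr3_aa
  )
}

#' Construct a TCR repertoire
#'
#' Builds a validated repertoire from a clonotype table. Rows sharing the
#' same clonotype key (CDR3 nucleotide sequence + V + J by default) are
#' merged by summing their UMI counts; merging is order-independent.
#'
#' @param clonotypes data.frame with columns `cdr3_nt`, `cdr3_aa`, `v_gene`,
#'   `d_gene`, `j_gene`, `count`, and optionally `productive`. Missing
#'   `cdr3_aa` entries are filled by translation; missing `productive` is
#'   inferred (in-frame and stop-free).
#' @param sample_id,group,subset sample metadata. `group` is conventionally
#'   one of "WT", "KO" or another label; `subset` e.g. "CD4_TEM", "CD8_TCM".
#' @param productive_only drop unproductive clonotypes (default TRUE:
#'   the analyses target expressed mRNA repertoires)
#' @param validate run invariant checks (count >= 1, translation consistency)
#' @return object of class `tcr_repertoire`: a list with elements
#'   `sample_id`, `group`, `subset`, `clonotypes` (data.frame) and
#'   `total_count` (sum of UMI counts)
#' @export
repertoire <- function(clonotypes, sample_id = "sample", group = "other",
                       subset = "other", productive_only = TRUE,
                       validate = TRUE) {
  cl <- as.data.frame(clonotypes, stringsAsFactors = FALSE)
  needed <- c("cdr3_nt", "v_gene", "j_gene", "count")
  miss <- setdiff(needed, names(cl))
  if (length(miss)) {
    stop("clonotype table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (!"d_gene" %in% names(cl)) cl$d_gene <- rep("", nrow(cl))
  cl$cdr3_nt <- toupper(as.character(cl$cdr3_nt))
  cl$d_gene[is.na(cl$d_gene)] <- ""
  cl$count <- as.integer(cl$count)
  if (nrow(cl) && any(is.na(cl$count) | cl$count < 1)) {
    stop("non-positive UMI count at row(s) ",
         paste(head(which(is.na(cl$count) | cl$count < 1), 5), collapse = ", "),
         " of sample ", sample_id)
  }
  if (!"cdr3_aa" %in% names(cl)) cl$cdr3_aa <- rep(NA_character_, nrow(cl))
  fill <- is.na(cl$cdr3_aa) | cl$cdr3_aa == ""
  if (any(fill)) cl$cdr3_aa[fill] <- translate_cdr3(cl$cdr3_nt[fill])
  if (!"productive" %in% names(cl)) {
    tr <- translate_cdr3(cl$cdr3_nt)
    cl$productive <- !is.na(tr) & !grepl("*", tr, fixed = TRUE)
  }
  cl$productive <- as.logical(cl$productive)
  if (productive_only && nrow(cl)) cl <- cl[cl$productive, , drop = FALSE]

  # merge rows sharing a key; first occurrence keeps the annotation
  if (nrow(cl)) {
    key <- clonotype_key(cl, "nt_vj")
    if (anyDuplicated(key)) {
      counts <- tapply(cl$count, key, sum)
      first <- cl[!duplicated(key), , drop = FALSE]
      first$count <- as.integer(counts[clonotype_key(first, "nt_vj")])
      cl <- first
    }
    cl <- cl[order(-cl$count, clonotype_key(cl, "nt_vj")), , drop = FALSE]
  }
  cl <- cl[, c("cdr3_nt", "cdr3_aa", "v_gene", "d_gene", "j_gene", "count",
               "productive")]
  rownames(cl) <- NULL

  rep <- structure(list(
    sample_id = as.character(sample_id),
    group = as.character(group),
    subset = as.character(subset),
    clonotypes = cl,
    total_count = if (nrow(cl)) sum(cl$count) else 0L
  ), class = "tcr_repertoire")
  if (validate) validate_repertoire(rep)
  rep
}

#' Validate repertoire invariants
#'
#' Checks key uniqueness, count positivity, total-count consistency and,
#' for productive clonotypes, that the amino-acid sequence equals the
#' standard-genetic-code translation of the nucleotide sequence with no
#' stop codon.
#'
#' @param rep a `tcr_repertoire`
#' @return `rep`, invisibly; errors on violation
#' @export
validate_repertoire <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  cl <- rep$clonotypes
  if (!nrow(cl)) {
    if (rep$total_count != 0L) stop("empty repertoire with nonzero total_count")
    return(invisible(rep))
  }
  if (any(cl$count < 1)) stop("clonotype with count < 1")
  if (anyDuplicated(clonotype_key(cl, "nt_vj"))) {
    stop("duplicate clonotype keys in repertoire ", rep$sample_id)
  }
  if (sum(cl$count) != rep$total_count) {
    stop("total_count does not equal sum of clonotype counts")
  }
  if (any(cl$v_gene == "" | cl$j_gene == "")) {
    stop("clonotype with empty v_gene or j_gene")
  }
  prod <- which(cl$productive)
  if (length(prod)) {
    if (any(nchar(cl$cdr3_nt[prod]) %% 3 != 0)) {
      stop("productive clonotype with out-of-frame junction length")
    }
    tr <- translate_cdr3(cl$cdr3_nt[prod])
    if (any(grepl("*", tr, fixed = TRUE))) {
      stop("productive clonotype translates with a stop codon")
    }
    if (any(tr != cl$cdr3_aa[prod])) {
      stop("productive clonotype where cdr3_aa != translation of cdr3_nt")
    }
  }
  invisible(rep)
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf(
    "<tcr_repertoire> %s [group=%s subset=%s] %d clonotypes, %d UMIs\n",
    x$sample_id, x$group, x$subset, nrow(x$clonotypes), x$total_count))
  invisible(x)
}

#' Number of unique clonotypes
#' @param rep a `tcr_repertoire`
#' @return integer richness
#' @export
richness <- function(rep) {
  nrow(rep$clonotypes)
}

#' Clonotype relative frequencies
#' @param rep a `tcr_repertoire`
#' @return numeric vector summing to 1 (count order of the table)
#' @export
clonotype_frequencies <- function(rep) {
  if (rep$total_count == 0L) stop("empty repertoire: frequencies undefined")
  rep$clonotypes$count / rep$total_count
}

# Resolve an index argument that may be a repertoire or a bare count
# vector; returns integer counts. Used by all diversity statistics.
.counts_of <- function(x) {
  if (inherits(x, "tcr_repertoire")) {
    cnt <- x$clonotypes$count
  } else {
    cnt <- x
  }
  cnt <- cnt[!is.na(cnt) & cnt > 0]
  if (!length(cnt)) stop("empty repertoire: statistic undefined")
  as.numeric(cnt)
}
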