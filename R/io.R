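#' Read an AIRR Rearrangement clonotype table
#'
#' Parses a tab-separated AIRR Rearrangement file carrying at least the
#' columns `junction`, `junction_aa`, `v_call`, `j_call` and
#' `duplicate_count` (`d_call` and `productive` are honored when present).
#' Gene names are normalized, rows sharing a clonotype key are merged by
#' summing UMI counts, and unproductive rows are dropped when
#' `productive_only`.
#'
#' @param path path to a TSV file
#' @param productive_only drop out-of-frame / stop-containing junctions
#'   (default TRUE)
#' @param sample_id,group,subset metadata; `sample_id` defaults to the file
#'   base name
#' @return a [repertoire()] object
#' @export
read_airr <- function(path, productive_only = TRUE,
                      sample_id = NULL, group = "other", subset = "other") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- data.table::fread(path, sep = "\t", colClasses = "character",
                           data.table = FALSE)
  required <- c("junction", "junction_aa", "v_call", "j_call",
                "duplicate_count")
  miss <- setdiff(required, names(tab))
  if (length(miss)) {
    stop("AIRR format error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(tsv|txt)$", "", basename(path))
  }
  cnt <- suppressWarnings(as.integer(tab$duplicate_count))
  bad <- which(is.na(cnt) | cnt < 1)
  if (length(bad)) {
    stop("invalid duplicate_count in ", path, " at data row(s) ",
         paste(head(bad, 5), collapse = ", "))
  }
  cl <- data.frame(
    cdr3_nt = toupper(tab$junction),
    cdr3_aa = tab$junction_aa,
    v_gene = normalize_gene_name(tab$v_call),
    d_gene = if ("d_call" %in% names(tab)) normalize_gene_name(tab$d_call) else "",
    j_gene = normalize_gene_name(tab$j_call),
    count = cnt,
    stringsAsFactors = FALSE
  )
  if ("productive" %in% names(tab)) {
    cl$productive <- tolower(as.character(tab$productive)) %in%
      c("t", "true", "1", "yes")
  }
  repertoire(cl, sample_id = sample_id, group = group, subset = subset,
             productive_only = productive_only)
}

#' Read a MiXCR/miTCR-style clonotype table
#'
#' Accepts the clones-table dialect with columns `cloneCount`, `nSeqCDR3`,
#' `aaSeqCDR3`, `allVHitsWithScore`, `allDHitsWithScore`,
#' `allJHitsWithScore`. For each hit column the best hit is taken: the text
#' before the first `(`, `*` or `,`.
#'
#' @inheritParams read_airr
#' @return a [repertoire()] object
#' @export
read_mixcr <- function(path, productive_only = TRUE,
                       sample_id = NULL, group = "other", subset = "other") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- data.table::fread(path, sep = "\t", data.table = FALSE)
  required <- c("cloneCount", "nSeqCDR3", "aaSeqCDR3", "allVHitsWithScore",
                "allJHitsWithScore")
  miss <- setdiff(required, names(tab))
  if (length(miss)) {
    stop("MiXCR format error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(tsv|txt)$", "", basename(path))
  }
  best_hit <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    sub("[(*,].*$", "", x)
  }
  cnt <- suppressWarnings(as.integer(round(as.numeric(tab$cloneCount))))
  bad <- which(is.na(cnt) | cnt < 1)
  if (length(bad)) {
    stop("invalid cloneCount in ", path, " at data row(s) ",
         paste(head(bad, 5), collapse = ", "))
  }
  cl <- data.frame(
    cdr3_nt = toupper(tab$nSeqCDR3),
    cdr3_aa = tab$aaSeqCDR3,
    v_gene = normalize_gene_name(best_hit(tab$allVHitsWithScore)),
    d_gene = if ("allDHitsWithScore" %in% names(tab)) {
      normalize_gene_name(best_hit(tab$allDHitsWithScore))
    } else "",
    j_gene = normalize_gene_name(best_hit(tab$allJHitsWithScore)),
    count = cnt,
    stringsAsFactors = FALSE
  )
  repertoire(cl, sample_id = sample_id, group = group, subset = subset,
             productive_only = productive_only)
}

#' Write a repertoire as AIRR Rearrangement TSV
#'
#' Emits columns `junction`, `junction_aa`, `v_call`, `d_call`, `j_call`,
#' `duplicate_count`, `productive`. Re-reading the file with [read_airr()]
#' reproduces the repertoire exactly (same keys and counts).
#'
#' @param rep a `tcr_repertoire`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_airr <- function(rep, path) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  cl <- rep$clonotypes
  out <- data.frame(
    junction = cl$cdr3_nt,
    junction_aa = cl$cdr3_aa,
    v_call = cl$v_gene,
    d_call = cl$d_gene,
    j_call = cl$j_gene,
    duplicate_count = cl$count,
    productive = ifelse(cl$productive, "T", "F"),
    stringsAsFactors = FALSE
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
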