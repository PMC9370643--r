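# BLAST tabular ("outfmt 6"-style, 12 columns) reading and hit filtering.

.blast_cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
                 "mismatches", "gap_opens", "q_start", "q_end", "s_start",
                 "s_end", "e_value", "bit_score")

#' Read a 12-column BLAST tabular hit file
#'
#' The standard tab-separated layout (query, subject, percent identity,
#' alignment length, mismatches, gap opens, query/subject coordinates,
#' e-value, bit score). Extra columns are ignored with a warning.
#'
#' @param path Path to the tabular file (no header).
#' @return A `data.frame` with the 12 standard columns.
#' @export
read_blast_hits <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  if (ncol(tab) < 12) {
    stop_canedet("BLAST tabular file must have >= 12 columns, found ", ncol(tab),
                 class = "canedet_format_error")
  }
  if (ncol(tab) > 12) {
    warning("ignoring ", ncol(tab) - 12, " extra BLAST column(s)", call. = FALSE)
    tab <- tab[, 1:12]
  }
  names(tab) <- .blast_cols
  validate_blast(tab)
}

validate_blast <- function(hits) {
  hits <- as.data.frame(hits, stringsAsFactors = FALSE)
  miss <- setdiff(.blast_cols, names(hits))
  if (length(miss)) {
    stop_canedet("BLAST table missing column(s): ", paste(miss, collapse = ", "),
                 class = "canedet_format_error")
  }
  if (any(hits$e_value < 0)) {
    stop_canedet("negative e-value(s)", class = "canedet_format_error")
  }
  if (any(hits$percent_identity < 0 | hits$percent_identity > 100)) {
    stop_canedet("percent_identity must lie in [0, 100]",
                 class = "canedet_format_error")
  }
  hits
}

#' Filter BLAST hits by e-value, identity and best-hit rule
#'
#' Keeps rows with `e_value <= max_evalue` and `percent_identity >
#' min_identity`. With `best_hit_only = TRUE` only the best row per query
#' survives: smallest e-value, ties broken by larger bit score, residual ties
#' by input order. Output is ordered by query (first-appearance order), so the
#' filter is idempotent.
#'
#' @param hits A BLAST hit `data.frame` as from [read_blast_hits()].
#' @param max_evalue E-value cut-off (default `1e-5`).
#' @param min_identity Identity threshold in percent, exclusive (default 70).
#' @param best_hit_only Keep only the best hit per query (default `TRUE`).
#' @return Filtered hit table (possibly zero rows).
#' @export
filter_blast_hits <- function(hits, max_evalue = 1e-5, min_identity = 70,
                              best_hit_only = TRUE) {
  hits <- validate_blast(hits)
  keep <- hits$e_value <= max_evalue & hits$percent_identity > min_identity
  out <- hits[keep, , drop = FALSE]
  if (best_hit_only && nrow(out) > 0) {
    ord <- order(match(out$query_id, unique(out$query_id)),
                 out$e_value, -out$bit_score, seq_len(nrow(out)))
    out <- out[ord, , drop = FALSE]
    out <- out[!duplicated(out$query_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
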