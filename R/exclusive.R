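# Genotype-exclusive expression: transcripts seen repeatedly in one genotype
# and never in the other.

#' Call genotype-exclusive transcripts
#'
#' A transcript is exclusive to a genotype when it has at least one read in at
#' least `min_positive_libraries` libraries of that genotype and zero reads in
#' every library of the other genotype; the rule is applied symmetrically in
#' both directions.
#'
#' @param matrix A [count_matrix()].
#' @param sheet A [sample_sheet()] partitioning the matrix's libraries into
#'   the two genotypes.
#' @param min_positive_libraries Minimum number of positive libraries in the
#'   expressing genotype (default 5, against the canonical 8 libraries per
#'   genotype).
#' @return Named character vector over the exclusive transcripts only, values
#'   `"EXCLUSIVE_HIGH_BNF"` or `"EXCLUSIVE_LOW_BNF"`.
#' @export
call_exclusive <- function(matrix, sheet, min_positive_libraries = 5) {
  stopifnot(inherits(matrix, "count_matrix"))
  high <- intersect(libraries_of(sheet, "HIGH_BNF"), library_ids(matrix))
  low <- intersect(libraries_of(sheet, "LOW_BNF"), library_ids(matrix))
  if (length(high) == 0 || length(low) == 0) {
    stop_canedet("sheet must supply libraries of both genotypes present in ",
                 "the matrix", class = "canedet_spec_error")
  }
  if (min_positive_libraries > max(length(high), length(low))) {
    stop_canedet("min_positive_libraries (", min_positive_libraries,
                 ") exceeds the library count of both genotypes",
                 class = "canedet_spec_error")
  }
  cm <- matrix$counts
  pos_high <- rowSums(cm[, high, drop = FALSE] >= 1)
  pos_low <- rowSums(cm[, low, drop = FALSE] >= 1)
  excl_high <- pos_high >= min_positive_libraries & pos_low == 0
  excl_low <- pos_low >= min_positive_libraries & pos_high == 0
  out <- c(
    stats::setNames(rep("EXCLUSIVE_HIGH_BNF", sum(excl_high)),
                    transcript_ids(matrix)[excl_high]),
    stats::setNames(rep("EXCLUSIVE_LOW_BNF", sum(excl_low)),
                    transcript_ids(matrix)[excl_low])
  )
  out[order(match(names(out), transcript_ids(matrix)))]
}
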