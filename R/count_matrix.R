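# Transcript x library read-count container and its on-disk TSV format.

#' Construct a validated count matrix
#'
#' Bundles a nonnegative integer matrix of reads per transcript per library
#' with per-transcript lengths (bp) and per-library totals (the RPKM
#' denominators). Library totals default to column sums, which is
#' self-contained and reproducible; a mapped- or sequenced-read total can be
#' supplied instead and must be at least the column sum.
#'
#' @param counts Integer matrix, transcripts in rows, libraries in columns;
#'   `rownames` are transcript ids, `colnames` are library ids.
#' @param lengths Named numeric vector of transcript lengths in bp covering
#'   every transcript (positive integers; a warning counts those below 100 bp,
#'   the assembly's minimum useful transcript length).
#' @param library_totals Optional named vector of per-library totals; defaults
#'   to column sums.
#' @return An object of class `count_matrix` (a list with elements `counts`,
#'   `lengths`, `library_totals`).
#' @export
count_matrix <- function(counts, lengths, library_totals = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_canedet("counts must have transcript rownames and library colnames",
                 class = "canedet_format_error")
  }
  if (anyDuplicated(rownames(counts))) {
    stop_canedet("duplicate transcript id(s): ",
                 paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                       collapse = ", "),
                 class = "canedet_duplicate_key_error")
  }
  if (anyDuplicated(colnames(counts))) {
    stop_canedet("duplicate library id(s)", class = "canedet_duplicate_key_error")
  }
  if (!is_count(counts)) {
    bad <- which(!(is.finite(counts) & counts >= 0 & counts == floor(counts)),
                 arr.ind = TRUE)[1, , drop = TRUE]
    stop_canedet("counts must be nonnegative integers; first offending cell: ",
                 "transcript '", rownames(counts)[bad[1]], "', library '",
                 colnames(counts)[bad[2]], "'",
                 class = "canedet_format_error")
  }
  storage.mode(counts) <- "double"

  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss)) {
    stop_canedet("transcript(s) missing a length: ",
                 paste(utils::head(miss, 10), collapse = ", "),
                 if (length(miss) > 10) ", ..." else "",
                 class = "canedet_missing_length_error")
  }
  lengths <- lengths[rownames(counts)]
  if (!is_count(lengths) || any(lengths < 1)) {
    stop_canedet("transcript lengths must be positive integers (bp)",
                 class = "canedet_format_error")
  }
  storage.mode(lengths) <- "double"
  n_short <- sum(lengths < 100)
  if (n_short > 0) {
    warning(n_short, " transcript(s) shorter than 100 bp", call. = FALSE)
  }

  colsum <- colSums(counts)
  if (is.null(library_totals)) {
    library_totals <- colsum
  } else {
    if (is.null(names(library_totals))) names(library_totals) <- colnames(counts)
    miss <- setdiff(colnames(counts), names(library_totals))
    if (length(miss)) {
      stop_canedet("library_totals missing for: ", paste(miss, collapse = ", "),
                   class = "canedet_format_error")
    }
    library_totals <- library_totals[colnames(counts)]
    if (any(library_totals < colsum)) {
      stop_canedet("library_totals below the column sum for: ",
                   paste(colnames(counts)[library_totals < colsum], collapse = ", "),
                   class = "canedet_format_error")
    }
  }
  if (any(library_totals < 1)) {
    stop_canedet("library_totals must be >= 1", class = "canedet_format_error")
  }

  structure(
    list(counts = counts, lengths = lengths,
         library_totals = library_totals),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "transcripts x", ncol(x$counts),
      "libraries\n")
  cat("  library totals:", paste0(format(x$library_totals, trim = TRUE),
                                  collapse = ", "), "\n")
  cat("  transcript length range:", min(x$lengths), "-", max(x$lengths), "bp\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

transcript_ids <- function(x) rownames(x$counts)
library_ids <- function(x) colnames(x$counts)

#' Read a count matrix from TSV
#'
#' Expected layout: header `transcript_id<TAB>LIB1<TAB>...`, one row per
#' transcript, integer counts. Lengths come either from a 2-column TSV
#' (`transcript_id`, `length_bp`) or a FASTA file (see [lengths_from_fasta()]);
#' the source must cover every transcript id exactly (no fuzzy matching).
#'
#' @param counts_path Path to the count TSV.
#' @param lengths_source Path to a lengths TSV or a FASTA file (`.fa`,
#'   `.fasta`, `.fna`), or a named numeric vector of lengths.
#' @param library_totals Optional named vector overriding the default
#'   column-sum totals.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, lengths_source, library_totals = NULL) {
  tab <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "")
  if (ncol(tab) < 2) {
    stop_canedet("count table needs a transcript_id column plus >= 1 library column",
                 class = "canedet_format_error")
  }
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[-1])
  if (!is.numeric(mat) || any(!is.finite(mat)) || any(mat < 0) ||
      any(mat != floor(mat))) {
    bad <- which(!(is.finite(mat) & mat >= 0 & mat == floor(mat)), arr.ind = TRUE)
    bad <- bad[1, , drop = TRUE]
    stop_canedet("non-integer or negative count at row ", bad[1], " ('",
                 ids[bad[1]], "'), column '", colnames(mat)[bad[2]], "'",
                 class = "canedet_format_error")
  }
  rownames(mat) <- ids

  if (is.character(lengths_source)) {
    lengths <- if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", lengths_source,
                         ignore.case = TRUE)) {
      lengths_from_fasta(lengths_source)
    } else {
      read_lengths_tsv(lengths_source)
    }
  } else {
    lengths <- lengths_source
  }
  count_matrix(mat, lengths, library_totals)
}

#' Read a two-column transcript-length TSV
#' @param path TSV with columns `transcript_id` and `length_bp` (header
#'   optional).
#' @return Named numeric vector of lengths.
#' @export
read_lengths_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("transcript|length|id", first, ignore.case = TRUE)
  tab <- utils::read.table(path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  if (anyDuplicated(tab[[1]])) {
    stop_canedet("duplicate transcript id(s) in length file",
                 class = "canedet_duplicate_key_error")
  }
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}

#' Transcript lengths from a FASTA file
#'
#' Ids are the header token before the first whitespace. A message reports how
#' many sequences fall below 100 bp (the assembly's minimum retained length).
#'
#' @param path FASTA file.
#' @return Named numeric vector of sequence lengths (bp).
#' @export
lengths_from_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) {
    stop_canedet("empty FASTA file: ", path, class = "canedet_empty_input_error")
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop_canedet("duplicate FASTA header id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "),
                 class = "canedet_duplicate_key_error")
  }
  len <- stats::setNames(Biostrings::width(seqs), ids)
  n_short <- sum(len < 100)
  if (n_short > 0) {
    warning(n_short, " sequence(s) shorter than 100 bp", call. = FALSE)
  }
  len
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_count_matrix()]: a `transcript_id` column followed by one
#' integer column per library. Lengths and (when not the default column sums)
#' library totals are written to side files next to the main table when
#' `lengths_path`/`totals_path` are given.
#'
#' @param x A [count_matrix()].
#' @param path Output TSV path.
#' @param lengths_path Optional path for a 2-column lengths TSV.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, lengths_path = NULL) {
  tab <- data.frame(transcript_id = transcript_ids(x),
                    x$counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(lengths_path)) {
    utils::write.table(
      data.frame(transcript_id = names(x$lengths), length_bp = x$lengths),
      lengths_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
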