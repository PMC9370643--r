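# Transcript -> functional-term annotation maps (GO / KEGG style).

.namespaces <- c("GO_BP", "GO_MF", "GO_CC", "KEGG", "CUSTOM")

#' Construct an annotation map
#'
#' A long-format map from transcript ids to functional terms (GO / KEGG /
#' custom namespaces). Duplicate (transcript, term) pairs are collapsed;
#' transcripts without annotation are simply absent.
#'
#' @param transcript_id,term_id Character vectors of equal length.
#' @param namespace Term namespace, one of `GO_BP`, `GO_MF`, `GO_CC`, `KEGG`,
#'   `CUSTOM` (recycled).
#' @return A `data.frame` of class `annotation_map` with the three columns,
#'   deduplicated.
#' @export
annotation_map <- function(transcript_id, term_id, namespace = "CUSTOM") {
  namespace <- toupper(namespace)
  if (!all(namespace %in% .namespaces)) {
    stop_canedet("unknown namespace value(s): ",
                 paste(setdiff(unique(namespace), .namespaces), collapse = ", "),
                 class = "canedet_vocabulary_error")
  }
  map <- data.frame(transcript_id = as.character(transcript_id),
                    term_id = as.character(term_id),
                    namespace = rep_len(namespace, length(transcript_id)),
                    stringsAsFactors = FALSE)
  map <- unique(map)
  rownames(map) <- NULL
  class(map) <- c("annotation_map", "data.frame")
  map
}

#' Read an annotation map
#'
#' Two formats are supported. `format = "tsv"`: three columns
#' `transcript_id`, `term_id`, `namespace` (header optional). `format =
#' "gmt"`: one term per line, `term<TAB>description<TAB>id1<TAB>id2...`, all
#' terms assigned to one `namespace`.
#'
#' @param path Input file.
#' @param format `"tsv"` (default) or `"gmt"`.
#' @param namespace Namespace assigned to GMT terms (default `"CUSTOM"`).
#' @return An [annotation_map()].
#' @export
read_annotation_map <- function(path, format = c("tsv", "gmt"),
                                namespace = "CUSTOM") {
  format <- match.arg(format)
  if (format == "tsv") {
    first <- readLines(path, n = 1L)
    has_header <- grepl("transcript_id", first, fixed = TRUE)
    tab <- utils::read.table(path, header = has_header, sep = "\t",
                             stringsAsFactors = FALSE, quote = "")
    if (ncol(tab) < 3) {
      stop_canedet("annotation TSV needs 3 columns (transcript_id, term_id, namespace)",
                   class = "canedet_format_error")
    }
    annotation_map(tab[[1]], tab[[2]], tab[[3]])
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(parts) < 3
    if (any(bad)) {
      stop_canedet("GMT line(s) with fewer than 3 fields: ",
                   paste(which(bad), collapse = ", "),
                   class = "canedet_format_error")
    }
    term <- vapply(parts, `[[`, "", 1L)
    ids <- lapply(parts, function(p) p[-(1:2)])
    annotation_map(unlist(ids), rep(term, lengths(ids)), namespace)
  }
}

#' Write an annotation map to 3-column TSV
#' @param map An [annotation_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_map <- function(map, path) {
  utils::write.table(as.data.frame(unclass(map)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("annotation_map:", length(unique(x$transcript_id)), "transcripts,",
      length(unique(x$term_id)), "terms\n")
  invisible(x)
}
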