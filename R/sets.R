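# Set algebra over DET lists: Venn partitions, same-direction intersections,
# and the summary-percentage arithmetic used in mapping tables.

#' A directional transcript set
#'
#' One DET list with per-transcript direction (`UP_A` = more expressed in the
#' high-BNF genotype, `UP_B` = in the low-BNF genotype).
#'
#' @param label Set label (comparison name).
#' @param transcript_id Character vector of member ids (no duplicates).
#' @param direction `"UP_A"` or `"UP_B"` per member.
#' @return A `data.frame` of class `directional_set` with attribute `label`.
#' @export
directional_set <- function(label, transcript_id, direction) {
  transcript_id <- as.character(transcript_id)
  direction <- as.character(direction)
  if (length(direction) != length(transcript_id)) {
    stop_canedet("transcript_id and direction lengths differ",
                 class = "canedet_format_error")
  }
  if (!all(direction %in% c("UP_A", "UP_B"))) {
    stop_canedet("direction must be UP_A or UP_B",
                 class = "canedet_vocabulary_error")
  }
  if (anyDuplicated(transcript_id)) {
    stop_canedet("a transcript may carry only one direction per set",
                 class = "canedet_duplicate_key_error")
  }
  out <- data.frame(transcript_id = transcript_id, direction = direction,
                    stringsAsFactors = FALSE)
  attr(out, "label") <- as.character(label)
  class(out) <- c("directional_set", "data.frame")
  out
}

#' @export
print.directional_set <- function(x, ...) {
  cat("directional set", attr(x, "label"), ":", nrow(x), "transcripts (",
      sum(x$direction == "UP_A"), "UP_A,", sum(x$direction == "UP_B"),
      "UP_B )\n")
  invisible(x)
}

#' Venn partition of 2-6 transcript sets
#'
#' Assigns every transcript in the union to exactly one region according to
#' its membership signature. By default the partition counts transcripts and
#' ignores direction; with `ignore_direction = FALSE` the elements are
#' (transcript, direction) pairs, so the same transcript called in opposite
#' directions in two sets lands in two different regions.
#'
#' @param sets A list of [directional_set()]s (2 to 6) with unique labels.
#' @param ignore_direction Treat membership by transcript id only (default
#'   `TRUE`).
#' @return An object of class `venn_partition`: a named list of regions
#'   (names are `&`-joined label signatures, e.g. `"A&B"`), each a character
#'   vector of element keys; empty regions are present and empty. A `counts`
#'   attribute carries the region sizes.
#' @export
venn_partition <- function(sets, ignore_direction = TRUE) {
  if (length(sets) < 2 || length(sets) > 6) {
    stop_canedet("venn_partition supports 2 to 6 sets",
                 class = "canedet_size_error")
  }
  labels <- vapply(sets, function(s) attr(s, "label"), "")
  if (anyDuplicated(labels)) {
    stop_canedet("set labels must be unique", class = "canedet_spec_error")
  }
  members <- lapply(sets, function(s) {
    if (ignore_direction) unique(s$transcript_id)
    else paste(s$transcript_id, s$direction, sep = "|")
  })
  universe <- unique(unlist(members))
  sig <- vapply(members, function(m) universe %in% m, logical(length(universe)))
  if (length(universe) == 1) sig <- matrix(sig, nrow = 1)

  k <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  regions <- stats::setNames(
    vector("list", nrow(combos)),
    apply(combos, 1, function(row) paste(labels[as.logical(row)], collapse = "&"))
  )
  key <- apply(sig, 1, function(row) paste(labels[row], collapse = "&"))
  for (nm in names(regions)) {
    regions[[nm]] <- universe[key == nm]
  }
  structure(regions, counts = lengths(regions), labels = labels,
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat("Venn partition over sets:", paste(attr(x, "labels"), collapse = ", "),
      "\n")
  for (nm in names(x)) cat(sprintf("  %-40s %d\n", nm, cnt[[nm]]))
  invisible(x)
}

#' Same-direction intersection of two DET sets
#'
#' Transcripts differentially expressed in both sets with the same genotype
#' direction — e.g. the DETs of naturally colonized stalks that keep their
#' pattern in the bacteria-free hydroponic data, which separates intrinsic
#' genotype differences from colonization responses.
#'
#' @param colonized,bacteria_free Two [directional_set()]s for the same
#'   genotype pair and tissue.
#' @return A [directional_set()] of the shared same-direction transcripts,
#'   labelled `"<label1>&<label2>"`.
#' @export
common_pattern <- function(colonized, bacteria_free) {
  merged <- merge(as.data.frame(colonized), as.data.frame(bacteria_free),
                  by = "transcript_id", suffixes = c(".1", ".2"))
  keep <- merged[merged$direction.1 == merged$direction.2, ]
  keep <- keep[order(match(keep$transcript_id, colonized$transcript_id)), ]
  directional_set(
    paste(attr(colonized, "label"), attr(bacteria_free, "label"), sep = "&"),
    keep$transcript_id, keep$direction.1
  )
}

#' Percentage with half-up rounding
#'
#' `100 * numerator / denominator`, rounded half-up to `decimals` places —
#' the convention of mapping-summary tables (e.g. loci mapped to another
#' species' proteome as a percentage of all loci).
#'
#' @param numerator Count `>= 0`.
#' @param denominator Count `>= 1`.
#' @param decimals Decimal places (default 2).
#' @return Percentage value(s).
#' @examples
#' mapping_percentage(43715, 53395)  # 81.87
#' @export
mapping_percentage <- function(numerator, denominator, decimals = 2) {
  if (any(denominator < 1)) {
    stop_canedet("denominator must be >= 1", class = "canedet_domain_error")
  }
  if (any(numerator < 0)) {
    stop_canedet("numerator must be >= 0", class = "canedet_domain_error")
  }
  round_half_up(100 * numerator / denominator, decimals)
}

#' Serialize a Venn partition to a structured text file
#'
#' One block per region: the signature, the count, and the member ids.
#'
#' @param partition A [venn_partition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_venn_partition <- function(partition, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cnt <- attr(partition, "counts")
  for (nm in names(partition)) {
    writeLines(sprintf("# region\t%s\t%d", nm, cnt[[nm]]), con)
    if (cnt[[nm]] > 0) writeLines(partition[[nm]], con)
  }
  invisible(path)
}
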