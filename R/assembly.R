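# Assembly summary statistics (sequence counts, mean length, N50).

#' Assembly summary statistics
#'
#' N50 follows the dominant convention: sort lengths in decreasing order and
#' report the length at which the cumulative sum first reaches at least half
#' the total assembly length.
#'
#' @param lengths Numeric vector of sequence lengths in bp (all >= 1).
#' @return An object of class `assembly_stats`: list with `n_sequences`,
#'   `total_length`, `mean_length`, `n50`.
#' @examples
#' compute_assembly_stats(c(5, 4, 3, 2, 1))  # N50 = 4
#' @export
compute_assembly_stats <- function(lengths) {
  if (length(lengths) == 0) {
    stop_canedet("empty length collection", class = "canedet_empty_input_error")
  }
  if (any(!is.finite(lengths)) || any(lengths < 1)) {
    stop_canedet("all lengths must be finite and >= 1 bp",
                 class = "canedet_format_error")
  }
  sorted <- sort(lengths, decreasing = TRUE)
  total <- sum(sorted)
  n50 <- sorted[which(cumsum(sorted) >= total / 2)[1]]
  structure(
    list(n_sequences = length(lengths),
         total_length = total,
         mean_length = total / length(lengths),
         n50 = n50),
    class = "assembly_stats"
  )
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("%d sequences, total %.0f bp, mean %.1f bp, N50 %.0f bp\n",
              x$n_sequences, x$total_length, x$mean_length, x$n50))
  invisible(x)
}
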