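# RPKM normalization and log2 fold change.

#' RPKM (reads per kilobase per million reads)
#'
#' `count * 1e9 / (library_total * length)`: reads scaled per million library
#' reads and per kilobase of transcript, so values are comparable across
#' libraries and transcripts. All arguments are vectorized.
#'
#' @param count Read count(s), `>= 0`.
#' @param length Transcript length(s) in bp, `>= 1`.
#' @param library_total Total reads in the library, `>= 1`.
#' @return RPKM value(s).
#' @examples
#' compute_rpkm(10, 500, 1e6)  # 20
#' @export
compute_rpkm <- function(count, length, library_total) {
  if (any(length < 1) || any(library_total < 1)) {
    stop_canedet("length and library_total must be >= 1",
                 class = "canedet_domain_error")
  }
  if (any(count < 0)) {
    stop_canedet("count must be >= 0", class = "canedet_domain_error")
  }
  count * 1e9 / (library_total * length)
}

#' Log2 fold change between two RPKM values
#'
#' `log2((rpkm_interest + pseudo) / (rpkm_control + pseudo))`. The pseudocount
#' keeps zero-expression transcripts reportable; with `pseudo = 0` both RPKMs
#' must be positive (transcripts absent from one side belong to the
#' exclusivity rule, not to a fold change).
#'
#' @param rpkm_interest,rpkm_control RPKM of the condition of interest and of
#'   the control.
#' @param pseudo Nonnegative RPKM offset added to both sides (default 0).
#' @return log2 ratio(s).
#' @export
log2_fold_change <- function(rpkm_interest, rpkm_control, pseudo = 0) {
  if (any(pseudo < 0)) {
    stop_canedet("pseudo must be >= 0", class = "canedet_domain_error")
  }
  if (any(pseudo == 0 & (rpkm_interest <= 0 | rpkm_control <= 0))) {
    stop_canedet("zero RPKM with pseudo = 0; use a pseudocount or the ",
                 "exclusivity rule", class = "canedet_domain_error")
  }
  log2((rpkm_interest + pseudo) / (rpkm_control + pseudo))
}
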