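# qPCR delta-Ct quantification with dual reference genes, and concordance of
# qPCR ratios with RNA-seq fold changes.

#' Relative expression from Ct values (delta-Ct method)
#'
#' `deltaCt = target_ct - mean(reference_cts)`; relative expression is
#' `efficiency^(-deltaCt)`. Averaging the two reference Cts arithmetically is
#' equivalent to normalizing by the geometric mean of the two reference
#' quantities (the usual dual-reference convention, here 28S rRNA and GAPDH).
#'
#' @param target_ct Numeric vector of target Ct values (cycles).
#' @param reference_cts Either a numeric vector (one reference per target
#'   value), or a matrix / data.frame with one row per target value and one
#'   column per reference gene.
#' @param efficiency Amplification factor per cycle, `> 1` (default 2 =
#'   perfect doubling).
#' @return Relative expression value(s), same length as `target_ct`.
#' @examples
#' relative_expression(24, cbind(25, 25))  # 2: one cycle earlier than refs
#' @export
relative_expression <- function(target_ct, reference_cts, efficiency = 2) {
  if (efficiency <= 1) {
    stop_canedet("efficiency must be > 1", class = "canedet_domain_error")
  }
  if (is.data.frame(reference_cts)) reference_cts <- as.matrix(reference_cts)
  ref_mean <- if (is.matrix(reference_cts)) rowMeans(reference_cts)
              else as.numeric(reference_cts)
  if (anyNA(target_ct) || anyNA(ref_mean)) {
    stop_canedet("missing Ct value(s)", class = "canedet_incomplete_record_error")
  }
  if (any(target_ct <= 0) || any(ref_mean <= 0)) {
    stop_canedet("Ct values must be finite and > 0",
                 class = "canedet_domain_error")
  }
  delta_ct <- target_ct - ref_mean
  efficiency^(-delta_ct)
}

#' Read a Ct table
#'
#' TSV with columns `sample_id`, `replicate`, `target_ct`, `ref1_ct`,
#' `ref2_ct`.
#'
#' @param path Input path.
#' @return A `data.frame` with those columns.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "replicate", "target_ct", "ref1_ct", "ref2_ct")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_canedet("Ct table missing column(s): ", paste(miss, collapse = ", "),
                 class = "canedet_format_error")
  }
  tab
}

#' Expression ratio between two samples with propagated dispersion
#'
#' `mean(a) / mean(b)` over the replicate relative-expression values of the
#' two samples, with the standard deviation propagated by the delta method
#' (`sd_ratio = ratio * sqrt(cv_a^2 + cv_b^2)` using per-replicate sds), plus
#' the log2 of the ratio for direct comparison with RNA-seq log2 fold changes.
#'
#' @param sample_a,sample_b Numeric vectors of replicate relative-expression
#'   values (at least 1 each).
#' @return List with `ratio`, `sd`, `log2_ratio`, `n_a`, `n_b`.
#' @export
expression_ratio <- function(sample_a, sample_b) {
  if (length(sample_a) < 1 || length(sample_b) < 1) {
    stop_canedet("need >= 1 replicate per side", class = "canedet_domain_error")
  }
  ma <- mean(sample_a)
  mb <- mean(sample_b)
  if (mb == 0) {
    stop_canedet("control sample mean is zero", class = "canedet_domain_error")
  }
  ratio <- ma / mb
  sa <- if (length(sample_a) > 1) stats::sd(sample_a) else 0
  sb <- if (length(sample_b) > 1) stats::sd(sample_b) else 0
  sd_ratio <- abs(ratio) * sqrt((sa / ma)^2 + (sb / mb)^2)
  list(ratio = ratio, sd = sd_ratio, log2_ratio = log2(ratio),
       n_a = length(sample_a), n_b = length(sample_b))
}

#' Sign concordance between qPCR and RNA-seq log2 ratios
#'
#' Fraction of shared transcripts whose qPCR log2 ratio and RNA-seq log2 fold
#' change have the same sign; an exact zero on either side matches nothing.
#'
#' @param qpcr_log2 Named numeric vector: transcript -> qPCR log2 ratio.
#' @param rnaseq_log2 Named numeric vector: transcript -> RNA-seq log2 fold
#'   change.
#' @return List with `fraction` (sign-agreement rate), `n_shared`, and
#'   `pairs` (data.frame of the paired values with an `agree` flag).
#' @export
concordance <- function(qpcr_log2, rnaseq_log2) {
  shared <- intersect(names(qpcr_log2), names(rnaseq_log2))
  if (length(shared) == 0) {
    stop_canedet("no shared transcripts", class = "canedet_empty_overlap_error")
  }
  q <- qpcr_log2[shared]
  r <- rnaseq_log2[shared]
  agree <- sign(q) == sign(r) & sign(q) != 0
  list(fraction = mean(agree), n_shared = length(shared),
       pairs = data.frame(transcript_id = shared, qpcr_log2 = unname(q),
                          rnaseq_log2 = unname(r), agree = unname(agree),
                          stringsAsFactors = FALSE))
}
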