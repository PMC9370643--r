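# DET calling: the full per-comparison differential-expression procedure.

#' Define a two-group comparison
#'
#' @param label Human-readable comparison name (e.g. `"ROOT.STALK"`).
#' @param group_a,group_b Disjoint, nonempty character vectors of library ids;
#'   group A is the condition of interest (high-BNF genotype by convention),
#'   group B the control.
#' @param replicate_mode `"POOLED"` (default): replicate counts are summed
#'   within each group and one test is run per transcript.
#'   `"PER_PAIR_CONSENSUS"`: every replicate pair across the groups is tested
#'   separately and a transcript is called only when significant with a
#'   consistent direction in all pairs.
#' @return An object of class `comparison_spec`.
#' @export
comparison_spec <- function(label, group_a, group_b,
                            replicate_mode = c("POOLED", "PER_PAIR_CONSENSUS")) {
  replicate_mode <- match.arg(replicate_mode)
  group_a <- as.character(group_a)
  group_b <- as.character(group_b)
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop_canedet("both groups must be nonempty", class = "canedet_spec_error")
  }
  if (length(intersect(group_a, group_b))) {
    stop_canedet("groups overlap: ",
                 paste(intersect(group_a, group_b), collapse = ", "),
                 class = "canedet_spec_error")
  }
  structure(list(label = as.character(label), group_a = group_a,
                 group_b = group_b, replicate_mode = replicate_mode),
            class = "comparison_spec")
}

#' @export
print.comparison_spec <- function(x, ...) {
  cat("comparison", x$label, "(", x$replicate_mode, "):",
      paste(x$group_a, collapse = "+"), "vs",
      paste(x$group_b, collapse = "+"), "\n")
  invisible(x)
}

# Canonical genotype contrasts: HIGH_BNF vs LOW_BNF within each
# tissue x growth-condition cell of a sample sheet.
#' Genotype comparisons for every tissue/condition cell
#'
#' Builds one [comparison_spec()] per tissue x growth-condition combination
#' present in the sheet, with the high-BNF libraries as group A.
#'
#' @param sheet A [sample_sheet()].
#' @param replicate_mode Passed to [comparison_spec()].
#' @return Named list of `comparison_spec` objects.
#' @export
genotype_comparisons <- function(sheet, replicate_mode = "POOLED") {
  cells <- unique(sheet[c("tissue", "growth_condition")])
  specs <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- sheet$tissue == cells$tissue[i] &
      sheet$growth_condition == cells$growth_condition[i]
    label <- paste(cells$tissue[i], cells$growth_condition[i], sep = ".")
    specs[[label]] <- comparison_spec(
      label,
      sheet$library_id[sel & sheet$genotype == "HIGH_BNF"],
      sheet$library_id[sel & sheet$genotype == "LOW_BNF"],
      replicate_mode
    )
  }
  specs
}

#' Call differentially expressed transcripts for one comparison
#'
#' The count-based procedure: counts are pooled within each group (POOLED
#' mode), RPKM is computed from pooled counts and totals, every transcript
#' with a nonzero pooled count in at least one group is tested with a
#' two-sided Fisher exact test, p-values are Bonferroni-adjusted over the
#' number of transcripts actually tested, and a transcript is called `UP_A` or
#' `UP_B` when the adjusted p-value is below `alpha`, the absolute log2 fold
#' change reaches `min_abs_log2fc`, and the direction follows the larger RPKM.
#'
#' In `PER_PAIR_CONSENSUS` mode every replicate pair across the two groups is
#' tested separately (Bonferroni within each pair); a transcript is called
#' only when it is significant with the same direction in every pair. The
#' reported statistics (counts, RPKM, fold change) are still the pooled ones;
#' `p_raw`/`p_adj` report the least favourable (maximum) pair value, the
#' binding constraint of the consensus rule.
#'
#' @param matrix A [count_matrix()].
#' @param spec A [comparison_spec()]; all ids must exist in the matrix.
#' @param alpha Significance threshold on the adjusted p-value (default 0.05).
#' @param min_abs_log2fc Minimum absolute log2 fold change for a call
#'   (default 0: none, significance alone decides).
#' @param pseudo RPKM pseudocount used for reporting fold changes of
#'   zero-expression transcripts (default 0.25).
#' @param sheet Optional [sample_sheet()]; when given, genotype-exclusive
#'   transcripts (see [call_exclusive()]) are flagged in the `exclusive`
#'   column.
#' @param min_positive_libraries Passed to [call_exclusive()] when `sheet` is
#'   given.
#' @return An object of class `det_table`: a list with the per-transcript
#'   `records` data.frame (columns `transcript_id`, `count_a`, `count_b`,
#'   `total_a`, `total_b`, `rpkm_a`, `rpkm_b`, `log2fc`, `p_raw`, `p_adj`,
#'   `call`, `exclusive`), the `comparison`, `alpha` and `m_tests`.
#' @export
call_dets <- function(matrix, spec, alpha = 0.05, min_abs_log2fc = 0,
                      pseudo = 0.25, sheet = NULL, min_positive_libraries = 5) {
  stopifnot(inherits(matrix, "count_matrix"), inherits(spec, "comparison_spec"))
  all_ids <- library_ids(matrix)
  ga <- spec$group_a[spec$group_a %in% all_ids]
  gb <- spec$group_b[spec$group_b %in% all_ids]
  if (length(ga) == 0 || length(gb) == 0) {
    stop_canedet("empty group after resolving library ids against the matrix",
                 class = "canedet_spec_error")
  }

  cm <- matrix$counts
  count_a <- rowSums(cm[, ga, drop = FALSE])
  count_b <- rowSums(cm[, gb, drop = FALSE])
  total_a <- sum(matrix$library_totals[ga])
  total_b <- sum(matrix$library_totals[gb])
  len <- matrix$lengths
  rpkm_a <- compute_rpkm(count_a, len, total_a)
  rpkm_b <- compute_rpkm(count_b, len, total_b)
  log2fc <- log2_fold_change(rpkm_a, rpkm_b, pseudo)

  tested <- which(count_a + count_b > 0)
  m_tests <- length(tested)
  p_raw <- rep(NA_real_, nrow(cm))
  p_adj <- rep(NA_real_, nrow(cm))
  call <- rep("NS", nrow(cm))

  if (spec$replicate_mode == "POOLED") {
    if (m_tests > 0) {
      p_raw[tested] <- fisher_exact_two_sided(count_a[tested], total_a,
                                              count_b[tested], total_b)
      p_adj[tested] <- adjust_bonferroni(p_raw[tested], m_tests)
      sig <- tested[p_adj[tested] < alpha &
                      abs(log2fc[tested]) >= min_abs_log2fc &
                      rpkm_a[tested] != rpkm_b[tested]]
      call[sig] <- ifelse(rpkm_a[sig] > rpkm_b[sig], "UP_A", "UP_B")
    }
  } else {
    pairs <- expand.grid(a = ga, b = gb, stringsAsFactors = FALSE)
    ok <- rep(TRUE, nrow(cm))
    dir_sign <- rep(0, nrow(cm))
    p_worst <- rep(0, nrow(cm))
    padj_worst <- rep(0, nrow(cm))
    for (j in seq_len(nrow(pairs))) {
      ca <- cm[, pairs$a[j]]
      cb <- cm[, pairs$b[j]]
      ta <- matrix$library_totals[[pairs$a[j]]]
      tb <- matrix$library_totals[[pairs$b[j]]]
      t_j <- which(ca + cb > 0)
      m_j <- length(t_j)
      ra <- compute_rpkm(ca, len, ta)
      rb <- compute_rpkm(cb, len, tb)
      fc_j <- log2_fold_change(ra, rb, pseudo)
      pj <- rep(NA_real_, nrow(cm))
      aj <- rep(NA_real_, nrow(cm))
      if (m_j > 0) {
        pj[t_j] <- fisher_exact_two_sided(ca[t_j], ta, cb[t_j], tb)
        aj[t_j] <- adjust_bonferroni(pj[t_j], m_j)
      }
      sig_j <- !is.na(aj) & aj < alpha & abs(fc_j) >= min_abs_log2fc & ra != rb
      s_j <- ifelse(ra > rb, 1, -1)
      consistent <- sig_j & (dir_sign == 0 | dir_sign == s_j)
      ok <- ok & consistent
      dir_sign[consistent & dir_sign == 0] <- s_j[consistent & dir_sign == 0]
      p_worst <- pmax(p_worst, ifelse(is.na(pj), 1, pj))
      padj_worst <- pmax(padj_worst, ifelse(is.na(aj), 1, aj))
    }
    p_raw[tested] <- p_worst[tested]
    p_adj[tested] <- padj_worst[tested]
    sig <- which(ok & dir_sign != 0)
    call[sig] <- ifelse(dir_sign[sig] > 0, "UP_A", "UP_B")
  }

  exclusive <- rep("NONE", nrow(cm))
  if (!is.null(sheet)) {
    excl <- call_exclusive(matrix, sheet,
                           min_positive_libraries = min_positive_libraries)
    hit <- match(names(excl), transcript_ids(matrix))
    exclusive[hit] <- ifelse(excl == "EXCLUSIVE_HIGH_BNF",
                             "EXCLUSIVE_A", "EXCLUSIVE_B")
  }

  records <- data.frame(
    transcript_id = transcript_ids(matrix),
    count_a = count_a, count_b = count_b,
    total_a = total_a, total_b = total_b,
    rpkm_a = rpkm_a, rpkm_b = rpkm_b,
    log2fc = log2fc, p_raw = p_raw, p_adj = p_adj,
    call = call, exclusive = exclusive,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(comparison = spec, records = records, alpha = alpha,
                 m_tests = m_tests, min_abs_log2fc = min_abs_log2fc,
                 pseudo = pseudo),
            class = "det_table")
}

#' @export
print.det_table <- function(x, ...) {
  n_up_a <- sum(x$records$call == "UP_A")
  n_up_b <- sum(x$records$call == "UP_B")
  cat("DET table for comparison", x$comparison$label,
      sprintf("(%s mode)\n", x$comparison$replicate_mode))
  cat(sprintf("  %d transcripts tested (Bonferroni m = %d), alpha = %g\n",
              x$m_tests, x$m_tests, x$alpha))
  cat(sprintf("  %d DETs: %d up in A, %d up in B\n",
              n_up_a + n_up_b, n_up_a, n_up_b))
  invisible(x)
}

#' @export
summary.det_table <- function(object, ...) {
  r <- object$records
  out <- list(
    label = object$comparison$label,
    n_transcripts = nrow(r),
    m_tests = object$m_tests,
    alpha = object$alpha,
    n_up_a = sum(r$call == "UP_A"),
    n_up_b = sum(r$call == "UP_B"),
    n_exclusive = sum(r$exclusive != "NONE")
  )
  class(out) <- "summary.det_table"
  out
}

#' @export
print.summary.det_table <- function(x, ...) {
  cat(sprintf("%s: %d/%d tested, %d up-A, %d up-B, %d exclusive\n",
              x$label, x$m_tests, x$n_transcripts, x$n_up_a, x$n_up_b,
              x$n_exclusive))
  invisible(x)
}

#' @export
as.data.frame.det_table <- function(x, ...) x$records

#' Transcripts called in a DET table, with direction
#'
#' @param det A `det_table`.
#' @return A [directional_set()] of the called transcripts (direction `UP_A`
#'   or `UP_B`), labelled by the comparison.
#' @export
det_set <- function(det) {
  r <- det$records[det$records$call != "NS", ]
  directional_set(det$comparison$label, r$transcript_id, r$call)
}

#' Write a DET table to TSV
#'
#' Fixed columns (comparison first), probabilities in scientific notation
#' with 6 significant digits.
#'
#' @param det A `det_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_det_table <- function(det, path) {
  r <- det$records
  out <- data.frame(comparison = det$comparison$label, r,
                    stringsAsFactors = FALSE)
  for (col in c("p_raw", "p_adj")) {
    out[[col]] <- ifelse(is.na(r[[col]]), "NA",
                         formatC(r[[col]], format = "e", digits = 5))
  }
  for (col in c("rpkm_a", "rpkm_b", "log2fc")) {
    out[[col]] <- formatC(r[[col]], format = "g", digits = 6)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
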