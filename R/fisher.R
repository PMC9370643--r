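# Two-sided Fisher exact test for 2x2 read-count tables, vectorized.
#
# The table for one transcript is
#     [ count_a, total_a - count_a ]
#     [ count_b, total_b - count_b ]
# and, conditional on all margins, count_a is hypergeometric. The two-sided
# p-value is the sum of the probabilities of all tables with the same margins
# whose probability does not exceed that of the observed table, the "<=" read
# with a relative tolerance of 1e-7 (the standard guard against ties being
# broken by floating-point noise). Because the hypergeometric pmf is unimodal,
# the excluded tables form one contiguous interval around the mode; its two
# end points are located by binary search on the log-pmf, so each test costs
# O(log support) pmf evaluations and whole vectors of tables are processed at
# once.

#' Two-sided Fisher exact test on pooled read counts
#'
#' Exact two-sided p-value for the 2x2 table `[count_a, total_a - count_a;
#' count_b, total_b - count_b]`, defined as the total hypergeometric
#' probability of all tables (margins fixed) at most as probable as the
#' observed one, with relative tolerance 1e-7 on the comparison. All four
#' arguments are vectorized and recycled.
#'
#' @param count_a,count_b Reads for the transcript in group A / group B.
#' @param total_a,total_b Library (or pooled-group) totals, `>= 1`.
#' @return Numeric vector of p-values in `[0, 1]`.
#' @examples
#' fisher_exact_two_sided(3, 4, 1, 4)  # 0.4857143
#' @export
fisher_exact_two_sided <- function(count_a, total_a, count_b, total_b) {
  n <- max(length(count_a), length(total_a), length(count_b), length(total_b))
  a <- rep_len(as.numeric(count_a), n)
  A <- rep_len(as.numeric(total_a), n)
  b <- rep_len(as.numeric(count_b), n)
  B <- rep_len(as.numeric(total_b), n)
  if (any(A < 1) || any(B < 1)) {
    stop_canedet("totals must be >= 1", class = "canedet_domain_error")
  }
  if (any(a < 0) || any(b < 0) || any(a > A) || any(b > B)) {
    stop_canedet("counts must satisfy 0 <= count <= total",
                 class = "canedet_domain_error")
  }

  k <- a + b
  lo <- pmax(0, k - B)
  hi <- pmin(k, A)
  mode <- floor((k + 1) * (A + 1) / (A + B + 2))
  mode <- pmax(lo, pmin(hi, mode))

  logd <- function(x) stats::dhyper(x, A, B, k, log = TRUE)
  thresh <- logd(a) + log1p(1e-7)

  p <- rep(1, n)
  mid_exists <- logd(mode) > thresh
  if (any(mid_exists)) {
    # M1: smallest x in [lo, mode] with log-pmf above the threshold.
    l <- lo; h <- mode
    repeat {
      act <- mid_exists & l < h
      if (!any(act)) break
      m <- (l + h) %/% 2
      above <- act & logd(m) > thresh
      h[above] <- m[above]
      adv <- act & !above
      l[adv] <- m[adv] + 1
    }
    m1 <- l
    # M2: largest x in [mode, hi] with log-pmf above the threshold.
    l <- mode; h <- hi
    repeat {
      act <- mid_exists & l < h
      if (!any(act)) break
      m <- (l + h + 1) %/% 2
      above <- act & logd(m) > thresh
      l[above] <- m[above]
      dec <- act & !above
      h[dec] <- m[dec] - 1
    }
    m2 <- h
    idx <- which(mid_exists)
    p[idx] <- stats::phyper(m1[idx] - 1, A[idx], B[idx], k[idx]) +
      stats::phyper(m2[idx], A[idx], B[idx], k[idx], lower.tail = FALSE)
  }
  pmin(pmax(p, 0), 1)
}

#' Bonferroni adjustment
#'
#' Multiplies each raw p-value by the number of tests `m` and caps at 1.
#' `m` defaults to the number of p-values supplied and may be larger (e.g. a
#' global correction across comparisons), never smaller.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @param m Bonferroni denominator; default `length(p_values)`.
#' @return Adjusted p-values, same order.
#' @export
adjust_bonferroni <- function(p_values, m = NULL) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop_canedet("p-values must lie in [0, 1]", class = "canedet_domain_error")
  }
  m <- m %||% length(p_values)
  if (m < 1) stop_canedet("m must be >= 1", class = "canedet_domain_error")
  if (m < length(p_values)) {
    stop_canedet("m must be at least the number of p-values",
                 class = "canedet_domain_error")
  }
  pmin(1, p_values * m)
}
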