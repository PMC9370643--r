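# Most-probable-number estimation from serial-dilution tube outcomes.
#
# Single-hit Poisson model: a tube inoculated with v mL of undiluted
# homogenate turns positive with probability 1 - exp(-c*v), where c is the
# organism concentration per mL. The MPN is the maximum-likelihood c; the
# log-likelihood is strictly concave in log(c), and its score function is
# strictly decreasing in c, so the MLE is found by bisection.

#' Describe a serial-dilution MPN assay
#'
#' @param dilution_exponents Integer vector of ten-fold dilution exponents
#'   (e.g. `-1:-9`); more negative means more dilute.
#' @param tubes_per_dilution Tubes inoculated per dilution (single positive
#'   integer, default 3; 1 matches one tube of semi-solid medium per
#'   dilution).
#' @param positives Number of positive tubes per dilution
#'   (`0 <= positives <= tubes_per_dilution`).
#' @param inoculum_volume Volume inoculated per tube in mL (default 0.1,
#'   i.e. 100 uL).
#' @param homogenate_factor mL of homogenate per g of tissue (default 10:
#'   1 g macerated in 9 mL saline, volumes additive).
#' @return An object of class `dilution_series`.
#' @export
dilution_series <- function(dilution_exponents, tubes_per_dilution = 3,
                            positives, inoculum_volume = 0.1,
                            homogenate_factor = 10) {
  dilution_exponents <- as.integer(dilution_exponents)
  tubes <- rep_len(as.integer(tubes_per_dilution), length(dilution_exponents))
  positives <- as.integer(positives)
  if (length(positives) != length(dilution_exponents)) {
    stop_canedet("positives must have one entry per dilution",
                 class = "canedet_format_error")
  }
  if (any(positives < 0) || any(positives > tubes)) {
    stop_canedet("positives must lie in [0, tubes_per_dilution]",
                 class = "canedet_data_error")
  }
  if (inoculum_volume <= 0 || homogenate_factor <= 0) {
    stop_canedet("volumes must be positive", class = "canedet_domain_error")
  }
  ord <- order(dilution_exponents, decreasing = TRUE)
  structure(
    list(dilution_exponents = dilution_exponents[ord],
         tubes_per_dilution = tubes[ord],
         positives = positives[ord],
         inoculum_volume = inoculum_volume,
         homogenate_factor = homogenate_factor,
         # mL of undiluted homogenate per tube at each dilution
         volumes = inoculum_volume * 10^dilution_exponents[ord]),
    class = "dilution_series"
  )
}

#' Read a dilution-series TSV
#'
#' Columns `exponent`, `tubes`, `positives`; assay-level settings are passed
#' as arguments.
#'
#' @param path Input path.
#' @param inoculum_volume,homogenate_factor See [dilution_series()].
#' @return A [dilution_series()].
#' @export
read_dilution_series <- function(path, inoculum_volume = 0.1,
                                 homogenate_factor = 10) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("exponent", "tubes", "positives")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_canedet("dilution table missing column(s): ",
                 paste(miss, collapse = ", "), class = "canedet_format_error")
  }
  dilution_series(tab$exponent, tab$tubes, tab$positives,
                  inoculum_volume, homogenate_factor)
}

#' @export
print.dilution_series <- function(x, ...) {
  cat("dilution series:", length(x$dilution_exponents), "dilutions, ",
      "pattern", paste0(x$positives, "/", x$tubes_per_dilution,
                        collapse = ", "), "\n")
  invisible(x)
}

# Score function d(loglik)/dc; strictly decreasing in c when the series is
# non-degenerate (some positives and some negatives).
mpn_score <- function(c, series) {
  v <- series$volumes
  p <- series$positives
  n <- series$tubes_per_dilution
  pos <- p > 0
  sum(p[pos] * v[pos] / expm1(c * v[pos])) - sum((n - p) * v)
}

#' Maximum-likelihood MPN estimate
#'
#' Maximizes the single-hit likelihood
#' `prod_i C(n_i, p_i) (1 - e^(-c v_i))^p_i (e^(-c v_i))^(n_i - p_i)` over the
#' concentration `c > 0` by bisection on the monotone score function,
#' bracketing `[1e-6, 1e15]` organisms/mL with relative tolerance 1e-9.
#' All-negative series return 0 with status `ALL_NEGATIVE`; all-positive
#' series return the upper bracket as a lower bound with status
#' `ALL_POSITIVE`. A log10-scale Wald confidence interval from the inverse
#' observed information is attached for non-degenerate series.
#'
#' @param series A [dilution_series()].
#' @param conf_level Confidence level for the log10 interval (default 0.95).
#' @return An object of class `mpn_estimate` with elements `mpn_per_ml`,
#'   `mpn_per_g`, `log10_ci`, `status`, `series`. Methods: `print`, `coef`
#'   (concentration per mL and per g), `confint` (on the per-mL scale).
#' @examples
#' s <- dilution_series(-2, tubes_per_dilution = 3, positives = 2)
#' mpn_estimate(s)  # closed form: -log(1 - 2/3) / 1e-3
#' @export
mpn_estimate <- function(series, conf_level = 0.95) {
  stopifnot(inherits(series, "dilution_series"))
  p <- series$positives
  n <- series$tubes_per_dilution
  lower <- 1e-6
  upper <- 1e15

  if (all(p == 0)) {
    return(new_mpn_estimate(0, series, status = "ALL_NEGATIVE"))
  }
  if (all(p == n)) {
    return(new_mpn_estimate(upper, series, status = "ALL_POSITIVE"))
  }

  # Bisection on log10(c): the score is positive below the MLE and negative
  # above it. 100 halvings of a 21-decade bracket leave a relative error far
  # below the 1e-9 target.
  lo <- log10(lower)
  hi <- log10(upper)
  if (mpn_score(lower, series) < 0) {
    c_hat <- lower
  } else if (mpn_score(upper, series) > 0) {
    c_hat <- upper
  } else {
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      if (mpn_score(10^mid, series) > 0) lo <- mid else hi <- mid
      if ((hi - lo) < 1e-13) break
    }
    c_hat <- 10^((lo + hi) / 2)
  }

  # Observed information on the log10 scale for the Wald interval.
  v <- series$volumes
  pos <- p > 0
  cv <- c_hat * v[pos]
  # -d2l/d(ln c)^2 = sum p * cv^2 * e^cv / (e^cv - 1)^2, evaluated on the log
  # scale so that strongly saturated dilutions (large cv) underflow to 0
  # instead of overflowing
  log_expm1 <- function(x) ifelse(x > 30, x, log(expm1(x)))
  info_u <- sum(exp(log(p[pos]) + 2 * log(cv) + cv - 2 * log_expm1(cv)))
  ci <- NULL
  if (info_u > 0) {
    sigma_log10 <- (1 / sqrt(info_u)) / log(10)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- log10(c_hat) + c(-1, 1) * z * sigma_log10
  }
  new_mpn_estimate(c_hat, series, status = "OK", log10_ci = ci,
                   conf_level = conf_level)
}

new_mpn_estimate <- function(c_hat, series, status, log10_ci = NULL,
                             conf_level = NA_real_) {
  structure(
    list(mpn_per_ml = c_hat,
         mpn_per_g = c_hat * series$homogenate_factor,
         log10_ci = log10_ci,
         conf_level = conf_level,
         status = status,
         series = series),
    class = "mpn_estimate"
  )
}

#' @export
print.mpn_estimate <- function(x, ...) {
  cat("MPN estimate:", format(x$mpn_per_ml, digits = 6), "organisms/mL",
      sprintf("(%s)\n", x$status))
  cat("  per g tissue (x", x$series$homogenate_factor, "mL/g):",
      format(x$mpn_per_g, digits = 6), "\n")
  if (!is.null(x$log10_ci)) {
    cat(sprintf("  %d%% CI (log10 per mL): [%.3f, %.3f]\n",
                round(100 * x$conf_level), x$log10_ci[1], x$log10_ci[2]))
  }
  invisible(x)
}

#' @export
coef.mpn_estimate <- function(object, ...) {
  c(mpn_per_ml = object$mpn_per_ml, mpn_per_g = object$mpn_per_g)
}

#' @export
confint.mpn_estimate <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$log10_ci)) {
    stop_canedet("no confidence interval for a degenerate series",
                 class = "canedet_domain_error")
  }
  if (!missing(level) && !isTRUE(all.equal(level, object$conf_level))) {
    object <- mpn_estimate(object$series, conf_level = level)
  }
  out <- matrix(10^object$log10_ci, nrow = 1,
                dimnames = list("mpn_per_ml",
                                sprintf("%.1f %%", 100 * c((1 - object$conf_level) / 2,
                                                           1 - (1 - object$conf_level) / 2))))
  out
}

#' Convert an MPN estimate to organisms per gram of tissue
#'
#' Multiplies the per-mL concentration by the homogenate factor (mL of
#' homogenate per g of tissue). All-positive estimates propagate as a lower
#' bound with a warning.
#'
#' @param estimate An [mpn_estimate()].
#' @param series Optional [dilution_series()] supplying the homogenate factor
#'   (defaults to the one stored in the estimate).
#' @return Organisms per g (numeric), with attribute `lower_bound = TRUE`
#'   when the series was all-positive.
#' @export
cfu_per_gram <- function(estimate, series = NULL) {
  series <- series %||% estimate$series
  out <- estimate$mpn_per_ml * series$homogenate_factor
  if (estimate$status == "ALL_POSITIVE") {
    warning("all tubes positive: value is a lower bound", call. = FALSE)
    attr(out, "lower_bound") <- TRUE
  }
  out
}
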