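# Independent oracles, deliberately implemented differently from the package
# code paths they check.

# Two-sided Fisher p by exhaustive enumeration of the hypergeometric support,
# pmf built from log-binomial coefficients.
fisher_enum_oracle <- function(a, A, b, B) {
  k <- a + b
  x <- max(0, k - B):min(k, A)
  logpmf <- lchoose(A, x) + lchoose(B, k - x) - lchoose(A + B, k)
  pmf <- exp(logpmf)
  d0 <- pmf[x == a]
  sum(pmf[pmf <= d0 * (1 + 1e-7)])
}

# Upper-tail hypergeometric P(X >= k) by direct summation of lchoose pmfs.
hyper_tail_oracle <- function(k, K, n, N) {
  x <- k:min(n, K)
  x <- x[x >= max(0, n - (N - K))]
  if (length(x) == 0) return(0)
  sum(exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)))
}

# MPN log-likelihood and a dense log-grid maximizer.
mpn_loglik <- function(conc, series) {
  v <- series$volumes
  p <- series$positives
  n <- series$tubes_per_dilution
  ll <- -(n - p) * conc * v
  pos <- p > 0
  ll[pos] <- ll[pos] + p[pos] * log(-expm1(-conc * v[pos]))
  sum(ll)
}

mpn_grid_oracle <- function(series, log10_range = c(-2, 6), n_grid = 1e5) {
  grid <- 10^seq(log10_range[1], log10_range[2], length.out = n_grid)
  ll <- vapply(grid, mpn_loglik, 0, series = series)
  grid[which.max(ll)]
}

# Membership-signature partition oracle: for every element of the union,
# record which sets contain it.
venn_signature_oracle <- function(member_list) {
  universe <- unique(unlist(member_list))
  sig <- vapply(universe, function(el) {
    paste(names(member_list)[vapply(member_list, function(m) el %in% m, TRUE)],
          collapse = "&")
  }, "")
  split(universe, sig)
}

# Small deterministic toy matrix used across tests: 3 transcripts, the
# canonical 16-library design, hand-set counts.
toy_matrix <- function() {
  sheet <- canonical_design()
  counts <- matrix(5L, nrow = 3, ncol = 16,
                   dimnames = list(c("t1", "t2", "t3"), sheet$library_id))
  list(matrix = count_matrix(counts, c(t1 = 1000, t2 = 1000, t3 = 1000),
                             stats::setNames(rep(10000, 16), sheet$library_id)),
       sheet = sheet)
}
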