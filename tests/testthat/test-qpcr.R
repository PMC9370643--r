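# Delta-Ct relative expression, expression ratios and RNA-seq concordance.

test_that("delta-Ct doubles or halves exactly per cycle at efficiency 2", {
  expect_equal(relative_expression(25, cbind(25, 25)), 1)
  expect_equal(relative_expression(24, cbind(25, 25)), 2)
  expect_equal(relative_expression(27, cbind(24, 26)), 0.25)
  # one unit of delta-Ct scales expression by the efficiency factor
  for (dct in c(-3, -1, 0.5, 2)) {
    expect_equal(relative_expression(25 + dct, cbind(25, 25)),
                 2^(-dct))
    expect_equal(relative_expression(25 + dct, cbind(25, 25), efficiency = 1.9),
                 1.9^(-dct))
  }
  expect_error(relative_expression(25, cbind(25, NA)),
               class = "canedet_incomplete_record_error")
  expect_error(relative_expression(25, cbind(25, 25), efficiency = 1),
               class = "canedet_domain_error")
})

test_that("expression ratios propagate replicate dispersion", {
  r <- expression_ratio(c(4, 4), c(1, 1))
  expect_equal(r$ratio, 4)
  expect_equal(r$log2_ratio, 2)
  expect_equal(r$sd, 0)

  same <- expression_ratio(c(2, 3, 4), c(2, 3, 4))
  expect_equal(same$ratio, 1)
  expect_equal(same$log2_ratio, 0)

  # delta-method check on noisy replicates
  set.seed(21)
  a <- rnorm(6, 8, 0.5)
  b <- rnorm(6, 2, 0.3)
  r2 <- expression_ratio(a, b)
  want_sd <- (mean(a) / mean(b)) *
    sqrt((sd(a) / mean(a))^2 + (sd(b) / mean(b))^2)
  expect_equal(r2$sd, want_sd)
  expect_error(expression_ratio(c(1, 2), c(0, 0)),
               class = "canedet_domain_error")
})

test_that("sign concordance counts matches and treats zeros as mismatches", {
  q <- c(t1 = 1, t2 = -2, t3 = 0.5, t4 = 1)
  r <- c(t1 = 2, t2 = -1, t3 = -0.5, t4 = 0, t5 = 3)
  cc <- concordance(q, r)
  expect_equal(cc$n_shared, 4)
  expect_equal(cc$fraction, 0.5)  # t1, t2 agree; t3 flips; t4 zero
  expect_error(concordance(c(a = 1), c(b = 1)),
               class = "canedet_empty_overlap_error")

  # randomized signs hover at 1/2 within 3 binomial sd
  set.seed(33)
  n <- 1000
  ids <- sprintf("x%04d", 1:n)
  q2 <- stats::setNames(sample(c(-1, 1), n, TRUE) * runif(n, 0.1, 3), ids)
  r2 <- stats::setNames(sample(c(-1, 1), n, TRUE) * runif(n, 0.1, 3), ids)
  frac <- concordance(q2, r2)$fraction
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("simulated Ct tables recover planted ratios", {
  # noiseless: exact recovery
  ct <- simulate_ct_table(c(g1 = 1, g2 = 4), noise_sd = 0, seed = 2)
  for (tx in c("g1", "g2")) {
    rel <- relative_expression(ct$target_ct[ct$transcript_id == tx],
                               cbind(ct$ref1_ct, ct$ref2_ct)[ct$transcript_id == tx, ])
    a <- rel[ct$sample_id[ct$transcript_id == tx] == "A"]
    b <- rel[ct$sample_id[ct$transcript_id == tx] == "B"]
    er <- expression_ratio(a, b)
    expect_equal(er$log2_ratio, log2(c(g1 = 1, g2 = 4)[[tx]]), tolerance = 1e-12)
  }

  # noisy: recovered log2 ratio within the error-propagation bound
  ct2 <- simulate_ct_table(c(g = 4), noise_sd = 0.2, n_replicates = 6, seed = 9)
  rel2 <- relative_expression(ct2$target_ct, cbind(ct2$ref1_ct, ct2$ref2_ct))
  er2 <- expression_ratio(rel2[ct2$sample_id == "A"], rel2[ct2$sample_id == "B"])
  # sd of a mean difference of Ct values: 0.2 * sqrt(2/6) on the log2 scale
  expect_lt(abs(er2$log2_ratio - 2), 3 * 0.2 * sqrt(2 / 6) * 1.5)

  tmp <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(sample_id = "A", replicate = 1,
                                target_ct = 25, ref1_ct = 25, ref2_ct = 24),
                     tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_ct_table(tmp)$ref2_ct, 24)
})
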