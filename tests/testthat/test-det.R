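# RPKM, fold change, DET calling and the exclusivity rule.

test_that("RPKM follows count * 1e9 / (total * length) and its invariances", {
  expect_equal(compute_rpkm(0, 500, 1e6), 0)
  expect_equal(compute_rpkm(10, 500, 1e6), 20)
  # exact-rational cross-check: 7e9 / (2345678 * 1405)
  expect_equal(compute_rpkm(7, 1405, 2345678), 7e9 / (2345678 * 1405),
               tolerance = 1e-15)
  # scale invariance in (count, total)
  for (k in c(2, 10, 1000)) {
    expect_equal(compute_rpkm(3 * k, 777, 12345 * k), compute_rpkm(3, 777, 12345))
  }
  # sum rule: sum_t rpkm_t * length_t = 1e9 when totals are column sums
  set.seed(3)
  counts <- matrix(rpois(40, 50), 20,
                   dimnames = list(sprintf("t%02d", 1:20), c("L1", "L2")))
  len <- stats::setNames(sample(200:2000, 20), rownames(counts))
  cm <- count_matrix(counts, len)
  for (lib in c("L1", "L2")) {
    rpkm <- compute_rpkm(counts[, lib], len, cm$library_totals[[lib]])
    expect_equal(sum(rpkm * len), 1e9)
  }
  expect_error(compute_rpkm(1, 0, 10), class = "canedet_domain_error")
})

test_that("log2 fold change honours the pseudocount policy", {
  expect_equal(log2_fold_change(20, 5, 0), 2)
  expect_equal(log2_fold_change(7.3, 7.3, 1), 0)
  expect_equal(log2_fold_change(0, 5, 0.25), log2(0.25 / 5.25))
  expect_error(log2_fold_change(0, 5, 0), class = "canedet_domain_error")
  expect_error(log2_fold_change(1, 1, -0.1), class = "canedet_domain_error")
})

test_that("pooled DET calls match hand-computed Fisher + Bonferroni on a toy", {
  # 3 transcripts: a = (100, 1, 10), b = (1, 100, 10), totals 10000 each
  counts <- cbind(A1 = c(100, 1, 10), B1 = c(1, 100, 10))
  rownames(counts) <- c("up_a", "up_b", "flat")
  cm <- count_matrix(counts, c(up_a = 1000, up_b = 1000, flat = 1000),
                     c(A1 = 10000, B1 = 10000))
  spec <- comparison_spec("toy", "A1", "B1")
  det <- call_dets(cm, spec)

  expect_equal(det$m_tests, 3)
  r <- det$records
  expect_equal(r$call, c("UP_A", "UP_B", "NS"))
  # p-values equal the enumeration oracle, Bonferroni m = 3
  for (i in 1:3) {
    p_oracle <- fisher_enum_oracle(r$count_a[i], 10000, r$count_b[i], 10000)
    expect_equal(r$p_raw[i], p_oracle, tolerance = 1e-12)
    expect_equal(r$p_adj[i], min(1, 3 * p_oracle), tolerance = 1e-12)
  }
  # direction follows the larger RPKM; significant calls are below alpha
  sig <- r$call != "NS"
  expect_true(all(r$p_adj[sig] < det$alpha))
  expect_true(all((r$rpkm_a > r$rpkm_b)[r$call == "UP_A"]))
  expect_true(all((r$rpkm_b > r$rpkm_a)[r$call == "UP_B"]))
})

test_that("a self-comparison yields zero calls", {
  toy <- toy_matrix()
  spec <- comparison_spec("null", toy$sheet$library_id[1:2],
                          toy$sheet$library_id[3:4])
  det <- call_dets(toy$matrix, spec)
  expect_equal(sum(det$records$call != "NS"), 0)
})

test_that("consensus mode drops a contradictory replicate, pooled mode may keep it", {
  # Replicates A1/A2 vs B1/B2. Transcript 'incons' is strongly up in A1 but
  # strongly down in A2; pooling hides the contradiction, per-pair consensus
  # does not. Transcript 'consis' is up in A consistently.
  counts <- cbind(A1 = c(400, 200, 10), A2 = c(0, 210, 10),
                  B1 = c(100, 10, 10), B2 = c(110, 12, 10))
  rownames(counts) <- c("incons", "consis", "flat")
  len <- stats::setNames(rep(1000, 3), rownames(counts))
  totals <- stats::setNames(rep(1e5, 4), colnames(counts))
  cm <- count_matrix(counts, len, totals)

  pooled <- call_dets(cm, comparison_spec("p", c("A1", "A2"), c("B1", "B2")))
  cons <- call_dets(cm, comparison_spec("c", c("A1", "A2"), c("B1", "B2"),
                                        replicate_mode = "PER_PAIR_CONSENSUS"))
  expect_equal(pooled$records$call[pooled$records$transcript_id == "incons"],
               "UP_A")
  expect_equal(cons$records$call[cons$records$transcript_id == "incons"], "NS")
  expect_equal(cons$records$call[cons$records$transcript_id == "consis"], "UP_A")
  expect_equal(cons$records$call[cons$records$transcript_id == "flat"], "NS")

  # direct rule application: consensus call must be significant with one
  # direction in all four pairs
  for (tx in rownames(counts)) {
    pair_sig <- c()
    pair_dir <- c()
    for (a in c("A1", "A2")) for (b in c("B1", "B2")) {
      tested <- counts[, a] + counts[, b] > 0
      p <- fisher_enum_oracle(counts[tx, a], 1e5, counts[tx, b], 1e5)
      pair_sig <- c(pair_sig, min(1, sum(tested) * p) < 0.05)
      pair_dir <- c(pair_dir, sign(counts[tx, a] - counts[tx, b]))
    }
    want <- if (all(pair_sig) && length(unique(pair_dir)) == 1 && pair_dir[1] != 0) {
      if (pair_dir[1] > 0) "UP_A" else "UP_B"
    } else "NS"
    expect_equal(cons$records$call[cons$records$transcript_id == tx], want,
                 info = tx)
  }
})

test_that("min_abs_log2fc gates calls without touching p-values", {
  counts <- cbind(A1 = c(60, 500), B1 = c(30, 100))
  rownames(counts) <- c("mild", "strong")
  cm <- count_matrix(counts, c(mild = 1000, strong = 1000),
                     c(A1 = 1e5, B1 = 1e5))
  spec <- comparison_spec("fc", "A1", "B1")
  free <- call_dets(cm, spec, min_abs_log2fc = 0)
  gated <- call_dets(cm, spec, min_abs_log2fc = 1.5)
  expect_equal(free$records$p_raw, gated$records$p_raw)
  expect_equal(free$records$call, c("UP_A", "UP_A"))
  expect_equal(gated$records$call, c("NS", "UP_A"))
})

test_that("the exclusivity rule is applied verbatim and symmetrically", {
  sheet <- canonical_design()
  high <- sheet$library_id[sheet$genotype == "HIGH_BNF"]
  low <- sheet$library_id[sheet$genotype == "LOW_BNF"]
  counts <- matrix(0L, nrow = 4, ncol = 16,
                   dimnames = list(c("ex_low5", "low4", "leak", "ex_high"),
                                   sheet$library_id))
  counts["ex_low5", low[1:5]] <- 3       # 5 of 8 LOW, zero HIGH -> exclusive
  counts["low4", low[1:4]] <- 3          # only 4 positive -> not exclusive
  counts["leak", low[1:6]] <- 3          # 6 LOW but 1 read in HIGH -> not
  counts["leak", high[1]] <- 1
  counts["ex_high", high[1:7]] <- 2      # 7 of 8 HIGH, zero LOW -> exclusive
  cm <- count_matrix(counts,
                     stats::setNames(rep(500, 4), rownames(counts)),
                     stats::setNames(rep(1000, 16), sheet$library_id))
  excl <- call_exclusive(cm, sheet)
  expect_equal(excl, c(ex_low5 = "EXCLUSIVE_LOW_BNF",
                       ex_high = "EXCLUSIVE_HIGH_BNF")[names(excl)])
  expect_setequal(names(excl), c("ex_low5", "ex_high"))

  expect_error(call_exclusive(cm, sheet, min_positive_libraries = 9),
               class = "canedet_spec_error")

  # flags propagate into DET records when the sheet is supplied
  det <- call_dets(cm, comparison_spec("x", high, low), sheet = sheet)
  r <- det$records
  expect_equal(r$exclusive[r$transcript_id == "ex_low5"], "EXCLUSIVE_B")
  expect_equal(r$exclusive[r$transcript_id == "ex_high"], "EXCLUSIVE_A")
  expect_equal(r$exclusive[r$transcript_id == "low4"], "NONE")
})

test_that("FWER is controlled when the counting model holds (Poisson noise)", {
  # 400 null matrices without overdispersion: the exact conditional test plus
  # Bonferroni should produce >= 1 call in at most ~5% of runs.
  n_runs <- 400
  hits <- 0
  for (r in seq_len(n_runs)) {
    cfg <- simulation_config(n_transcripts = 200, library_totals = 5e4,
                             nb_dispersion = 0, de_fraction = 0,
                             exclusive_fraction = 0, seed = 20000 + r)
    sim <- simulate_experiment(cfg)
    spec <- genotype_comparisons(sim$sheet)[["ROOT.STALK"]]
    det <- call_dets(sim$matrix, spec)
    if (any(det$records$call != "NS")) hits <- hits + 1
  }
  expect_lte(hits / n_runs, 0.05 + 2 * sqrt(0.05 * 0.95 / n_runs))
})

test_that("DET tables serialize with fixed columns and 6-digit probabilities", {
  toy <- toy_matrix()
  det <- call_dets(toy$matrix,
                   comparison_spec("demo", toy$sheet$library_id[1:2],
                                   toy$sheet$library_id[15:16]))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_det_table(det, tmp)
  back <- utils::read.table(tmp, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expect_equal(names(back),
               c("comparison", "transcript_id", "count_a", "count_b",
                 "total_a", "total_b", "rpkm_a", "rpkm_b", "log2fc",
                 "p_raw", "p_adj", "call", "exclusive"))
  expect_equal(back$p_raw, det$records$p_raw, tolerance = 1e-5)
})
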