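# The synthetic-data generators and their ground-truth guarantees.

test_that("generators are pure functions of (config, seed)", {
  cfg <- simulation_config(n_transcripts = 150, library_totals = 2e4, seed = 42)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$matrix$counts, s2$matrix$counts)
  expect_identical(s1$truth, s2$truth)

  a1 <- simulate_annotation(s1$truth, seed = 5)
  a2 <- simulate_annotation(s1$truth, seed = 5)
  expect_identical(as.data.frame(unclass(a1)), as.data.frame(unclass(a2)))
  a3 <- simulate_annotation(s1$truth, seed = 6)
  expect_false(identical(as.data.frame(unclass(a1)),
                         as.data.frame(unclass(a3))))
})

test_that("a null configuration with Poisson noise has matched group means", {
  cfg <- simulation_config(n_transcripts = 100, library_totals = 1e5,
                           nb_dispersion = 0, de_fraction = 0,
                           exclusive_fraction = 0, seed = 13)
  sim <- simulate_experiment(cfg)
  sheet <- sim$sheet
  high <- sheet$library_id[sheet$genotype == "HIGH_BNF"]
  low <- sheet$library_id[sheet$genotype == "LOW_BNF"]
  a <- rowSums(sim$matrix$counts[, high])
  b <- rowSums(sim$matrix$counts[, low])
  # each group pools 8 Poisson draws around the same mean: difference within
  # 4 standard errors for every transcript (joint over 100 transcripts)
  se <- sqrt(a + b + 1)
  expect_true(all(abs(a - b) <= 4.5 * se))
})

test_that("planted exclusive transcripts obey the rule by construction", {
  cfg <- simulation_config(n_transcripts = 1000, library_totals = 5e4,
                           exclusive_fraction = 0.1, seed = 77)
  sim <- simulate_experiment(cfg)
  planted <- sim$truth$transcript_id[grepl("EXCLUSIVE", sim$truth$status)]
  expect_equal(length(planted), 100)
  called <- call_exclusive(sim$matrix, sim$sheet)
  # every planted exclusive is recovered, with the planted genotype
  expect_true(all(planted %in% names(called)))
  side <- sim$truth$status[match(names(called), sim$truth$transcript_id)]
  expect_equal(unname(called[side == "EXCLUSIVE_HIGH"]),
               rep("EXCLUSIVE_HIGH_BNF", sum(side == "EXCLUSIVE_HIGH")))
  # zero counts in the excluded genotype are structural
  low <- sim$sheet$library_id[sim$sheet$genotype == "LOW_BNF"]
  ex_high <- sim$truth$transcript_id[sim$truth$status == "EXCLUSIVE_HIGH"]
  expect_true(all(sim$matrix$counts[ex_high, low] == 0))
})

test_that("planted fold changes shift pooled group means as configured", {
  cfg <- simulation_config(n_transcripts = 500, library_totals = 1e6,
                           de_fraction = 0.2, de_log2fc = 2, seed = 3)
  sim <- simulate_experiment(cfg)
  sheet <- sim$sheet
  high <- sheet$library_id[sheet$genotype == "HIGH_BNF"]
  low <- sheet$library_id[sheet$genotype == "LOW_BNF"]
  up_high <- sim$truth$status == "DE_UP_HIGH" & sim$truth$base_mean > 50
  ratio <- rowSums(sim$matrix$counts[up_high, high]) /
    pmax(1, rowSums(sim$matrix$counts[up_high, low]))
  # log2 of the pooled ratio concentrates near the planted +2
  expect_lt(abs(stats::median(log2(ratio)) - 2), 0.35)
})

test_that("annotation maps plant exactly one enriched term", {
  cfg <- simulation_config(n_transcripts = 2000, library_totals = 1e4, seed = 8)
  sim <- simulate_experiment(cfg)
  ann <- simulate_annotation(sim$truth, n_terms = 20, planted_term_effect = 10,
                             seed = 9)
  de <- sim$truth$status %in% c("DE_UP_HIGH", "DE_UP_LOW")
  planted <- attr(ann, "planted_term")
  rate_de <- mean(sim$truth$transcript_id[de] %in%
                    ann$transcript_id[ann$term_id == planted])
  rate_bg <- mean(sim$truth$transcript_id[!de] %in%
                    ann$transcript_id[ann$term_id == planted])
  expect_gt(rate_de, 3 * rate_bg)
  # a null effect leaves the rates comparable
  ann0 <- simulate_annotation(sim$truth, n_terms = 20, planted_term_effect = 1,
                              seed = 9)
  r_de0 <- mean(sim$truth$transcript_id[de] %in%
                  ann0$transcript_id[ann0$term_id == attr(ann0, "planted_term")])
  r_bg0 <- mean(sim$truth$transcript_id[!de] %in%
                  ann0$transcript_id[ann0$term_id == attr(ann0, "planted_term")])
  expect_lt(abs(r_de0 - r_bg0), 0.05)
  # n_terms = 1 covers every transcript
  ann1 <- simulate_annotation(sim$truth, n_terms = 1, seed = 2)
  expect_setequal(unique(ann1$transcript_id), sim$truth$transcript_id)
})

test_that("the fixture bundle writes every pipeline input", {
  tmp <- withr::local_tempdir()
  cfg <- simulation_config(n_transcripts = 50, library_totals = 5e3, seed = 4)
  write_simulation_bundle(cfg, tmp)
  for (f in c("counts.tsv", "lengths.tsv", "sample_sheet.tsv",
              "annotation.tsv", "truth.tsv")) {
    expect_true(file.exists(file.path(tmp, f)), info = f)
  }
  cm <- read_count_matrix(file.path(tmp, "counts.tsv"),
                          file.path(tmp, "lengths.tsv"))
  expect_equal(dim(cm), c(50L, 16L))
})
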