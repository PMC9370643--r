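# Synthetic-data generators: count matrices with the canonical 16-library
# design and planted ground truth, annotation maps with a planted enriched
# term, serial-dilution outcomes, and Ct tables.
#
# All generators are pure functions of (config, seed): one master seed spawns
# fixed per-component substreams (lengths, baseline expression, truth
# assignment, counts, ...), so regenerating any component is stable across
# runs.

#' Configuration for a simulated experiment
#'
#' Defaults emulate a scaled-down version of the study design this package
#' models: the canonical 16-library sheet (2 genotypes x 2 tissues x 2 growth
#' conditions x 2 replicates), one million reads per library, log-normal
#' baseline expression spanning several orders of magnitude, negative-binomial
#' counting noise with dispersion 0.1 (variance `mu + 0.1 mu^2`), 10% of
#' transcripts differentially expressed between the genotypes at |log2FC| = 2,
#' and 2% genotype-exclusive.
#'
#' @param n_transcripts Number of transcripts (default 2000).
#' @param design A [sample_sheet()] (default [canonical_design()]).
#' @param library_totals Target reads per library, recycled over libraries
#'   (default 1e6). Per-transcript means are scaled so the expected column sum
#'   equals this; the emitted matrix uses its realized column sums as totals.
#' @param baseline_log2_mean,baseline_log2_sd Normal parameters of the
#'   per-transcript baseline log2 relative expression (defaults 4 and 2; only
#'   the spread matters, means are renormalized to the library total).
#' @param nb_dispersion NB dispersion phi, variance `mu + phi mu^2`
#'   (default 0.1; 0 gives Poisson counts).
#' @param de_fraction Fraction of transcripts with a planted genotype effect
#'   (default 0.1, split evenly between the two directions).
#' @param de_log2fc Planted |log2 fold change| (default 2).
#' @param exclusive_fraction Fraction of genotype-exclusive transcripts
#'   (default 0.02, split evenly).
#' @param transcript_length_range Uniform length range in bp
#'   (default `c(200, 5000)`).
#' @param min_positive_libraries Exclusive transcripts are guaranteed at
#'   least one read in this many libraries of the expressing genotype
#'   (default 5).
#' @param seed Master seed (default 1).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_transcripts = 2000,
                              design = canonical_design(),
                              library_totals = 1e6,
                              baseline_log2_mean = 4,
                              baseline_log2_sd = 2,
                              nb_dispersion = 0.1,
                              de_fraction = 0.1,
                              de_log2fc = 2,
                              exclusive_fraction = 0.02,
                              transcript_length_range = c(200, 5000),
                              min_positive_libraries = 5,
                              seed = 1) {
  if (de_fraction < 0 || exclusive_fraction < 0 ||
      de_fraction + exclusive_fraction > 1) {
    stop_canedet("fractions must be in [0,1] with de + exclusive <= 1",
                 class = "canedet_config_error")
  }
  if (n_transcripts < 1 || any(library_totals < 1)) {
    stop_canedet("need >= 1 transcript and positive library totals",
                 class = "canedet_config_error")
  }
  if (nb_dispersion < 0) {
    stop_canedet("nb_dispersion must be >= 0", class = "canedet_config_error")
  }
  structure(
    list(n_transcripts = n_transcripts, design = design,
         library_totals = library_totals,
         baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd,
         nb_dispersion = nb_dispersion, de_fraction = de_fraction,
         de_log2fc = de_log2fc, exclusive_fraction = exclusive_fraction,
         transcript_length_range = transcript_length_range,
         min_positive_libraries = min_positive_libraries,
         seed = seed),
    class = "simulation_config"
  )
}

#' Simulate a full experiment with known ground truth
#'
#' Draws negative-binomial counts whose genotype-specific means encode the
#' planted effects: differential transcripts have the up-genotype mean
#' multiplied by `2^de_log2fc` in every library of that genotype; exclusive
#' transcripts have mean zero in the excluded genotype and are guaranteed at
#' least one read in `min_positive_libraries` libraries of the other, so they
#' satisfy the exclusivity rule by construction.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `matrix` (a [count_matrix()]), `sheet` (the
#'   design), and `truth` (data.frame: `transcript_id`, `status` in
#'   `NULL_`/`DE_UP_HIGH`/`DE_UP_LOW`/`EXCLUSIVE_HIGH`/`EXCLUSIVE_LOW`,
#'   `true_log2fc`, `base_mean` = per-library baseline mean, `length`).
#' @export
simulate_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_transcripts
  sheet <- config$design
  libs <- sheet$library_id
  n_lib <- length(libs)
  totals <- rep_len(config$library_totals, n_lib)
  ids <- sprintf("TX%05d", seq_len(n))
  high <- sheet$genotype == "HIGH_BNF"
  low <- sheet$genotype == "LOW_BNF"

  lengths <- with_seed(substream_seed(config$seed, 1), {
    stats::setNames(sample(config$transcript_length_range[1]:
                             config$transcript_length_range[2],
                           n, replace = TRUE), ids)
  })

  base_log2 <- with_seed(substream_seed(config$seed, 2), {
    stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
  })
  w <- 2^base_log2
  w <- w / sum(w)

  n_de <- round(config$de_fraction * n)
  n_ex <- round(config$exclusive_fraction * n)
  status <- rep("NULL_", n)
  planted <- with_seed(substream_seed(config$seed, 3), sample(n, n_de + n_ex))
  de <- planted[seq_len(n_de)]
  ex <- planted[n_de + seq_len(n_ex)]
  status[de[seq_len(ceiling(n_de / 2))]] <- "DE_UP_HIGH"
  status[de[setdiff(seq_len(n_de), seq_len(ceiling(n_de / 2)))]] <- "DE_UP_LOW"
  status[ex[seq_len(ceiling(n_ex / 2))]] <- "EXCLUSIVE_HIGH"
  status[ex[setdiff(seq_len(n_ex), seq_len(ceiling(n_ex / 2)))]] <- "EXCLUSIVE_LOW"

  # Per-transcript, per-library means.
  mu <- outer(w, totals)
  fc_mult <- 2^config$de_log2fc
  mu[status == "DE_UP_HIGH", high] <- mu[status == "DE_UP_HIGH", high] * fc_mult
  mu[status == "DE_UP_LOW", low] <- mu[status == "DE_UP_LOW", low] * fc_mult
  mu[status == "EXCLUSIVE_HIGH", low] <- 0
  mu[status == "EXCLUSIVE_LOW", high] <- 0

  counts <- with_seed(substream_seed(config$seed, 4), {
    x <- if (config$nb_dispersion > 0) {
      stats::rnbinom(length(mu), mu = as.vector(mu),
                     size = 1 / config$nb_dispersion)
    } else {
      stats::rpois(length(mu), as.vector(mu))
    }
    matrix(x, nrow = n, dimnames = list(ids, libs))
  })

  # Guarantee the exclusivity rule for planted exclusive transcripts.
  for (g in c("EXCLUSIVE_HIGH", "EXCLUSIVE_LOW")) {
    cols <- which(if (g == "EXCLUSIVE_HIGH") high else low)
    for (i in which(status == g)) {
      pos <- counts[i, cols] >= 1
      need <- config$min_positive_libraries - sum(pos)
      if (need > 0) {
        fill <- cols[!pos][seq_len(need)]
        counts[i, fill] <- 1
      }
    }
  }

  true_log2fc <- ifelse(status == "DE_UP_HIGH", config$de_log2fc,
                        ifelse(status == "DE_UP_LOW", -config$de_log2fc, 0))
  truth <- data.frame(
    transcript_id = ids, status = status, true_log2fc = true_log2fc,
    base_mean = w * mean(totals), length = unname(lengths),
    stringsAsFactors = FALSE
  )
  list(matrix = count_matrix(counts, lengths), sheet = sheet, truth = truth)
}

#' Simulate an annotation map with one planted enriched term
#'
#' Terms annotate transcripts independently at `base_rate`; the first term
#' (`planted_term`, attribute of the result) annotates differentially
#' expressed transcripts (statuses `DE_UP_HIGH`/`DE_UP_LOW`) at the odds
#' `planted_term_effect` relative to the base rate, so a DET foreground is
#' enriched for it.
#'
#' @param truth Truth table from [simulate_experiment()].
#' @param n_terms Number of terms (default 20).
#' @param planted_term_effect Enrichment odds ratio for the planted term
#'   (default 10; 1 = no effect).
#' @param base_rate Per-term annotation probability (default 0.05).
#' @param seed RNG seed.
#' @return An [annotation_map()] (namespace `CUSTOM`) with attributes
#'   `planted_term` and `background` (all transcript ids).
#' @export
simulate_annotation <- function(truth, n_terms = 20, planted_term_effect = 10,
                                base_rate = 0.05, seed = 1) {
  if (n_terms < 1) {
    stop_canedet("n_terms must be >= 1", class = "canedet_config_error")
  }
  ids <- truth$transcript_id
  de <- truth$status %in% c("DE_UP_HIGH", "DE_UP_LOW")
  terms <- sprintf("TERM%03d", seq_len(n_terms))
  q <- base_rate
  q_planted <- planted_term_effect * q / (1 - q + planted_term_effect * q)
  with_seed(seed, {
    tx <- character(0)
    tm <- character(0)
    for (j in seq_len(n_terms)) {
      pr <- if (j == 1 && n_terms > 1) ifelse(de, q_planted, q) else q
      if (n_terms == 1) pr <- 1  # degenerate map: the single term covers all
      hit <- stats::runif(length(ids)) < pr
      tx <- c(tx, ids[hit])
      tm <- c(tm, rep(terms[j], sum(hit)))
    }
    map <- annotation_map(tx, tm, "CUSTOM")
    attr(map, "planted_term") <- terms[1]
    attr(map, "background") <- ids
    map
  })
}

#' Simulate serial-dilution tube outcomes at a known concentration
#'
#' Each tube at dilution `i` turns positive independently with probability
#' `1 - exp(-true_conc * v_i)` (single-hit Poisson model), where `v_i` is the
#' volume of undiluted homogenate delivered to the tube.
#'
#' @param true_conc True concentration in organisms/mL of homogenate.
#' @param series_spec A [dilution_series()] supplying the geometry (its
#'   `positives` are ignored).
#' @param seed RNG seed.
#' @return A [dilution_series()] with simulated `positives`.
#' @export
simulate_dilution_series <- function(true_conc, series_spec, seed = 1) {
  if (true_conc < 0) {
    stop_canedet("true_conc must be >= 0", class = "canedet_config_error")
  }
  p_pos <- -expm1(-true_conc * series_spec$volumes)
  positives <- with_seed(seed, {
    stats::rbinom(length(p_pos), series_spec$tubes_per_dilution, p_pos)
  })
  dilution_series(series_spec$dilution_exponents,
                  series_spec$tubes_per_dilution, positives,
                  series_spec$inoculum_volume, series_spec$homogenate_factor)
}

#' Simulate a two-sample Ct table at known expression ratios
#'
#' Reference Cts are constant at `base_ct`; target Cts in sample A are offset
#' by `-log2(ratio)` relative to sample B, plus Gaussian noise, so the
#' delta-Ct method recovers the planted ratio up to noise.
#'
#' @param true_ratios Named numeric vector: transcript -> A/B expression
#'   ratio (all > 0).
#' @param base_ct Reference Ct level in cycles (default 25).
#' @param noise_sd Gaussian Ct noise in cycles (default 0.2).
#' @param n_replicates Replicates per sample (default 3).
#' @param seed RNG seed.
#' @return Data frame with columns `sample_id` (`"A"`/`"B"`),
#'   `transcript_id`, `replicate`, `target_ct`, `ref1_ct`, `ref2_ct`.
#' @export
simulate_ct_table <- function(true_ratios, base_ct = 25, noise_sd = 0.2,
                              n_replicates = 3, seed = 1) {
  if (any(true_ratios <= 0)) {
    stop_canedet("ratios must be > 0", class = "canedet_config_error")
  }
  tx <- names(true_ratios) %||% sprintf("TX%03d", seq_along(true_ratios))
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      transcript_id = tx, sample_id = c("A", "B"),
                      stringsAsFactors = FALSE)
  offset <- ifelse(grid$sample_id == "A",
                   -log2(true_ratios[grid$transcript_id]), 0)
  with_seed(seed, {
    grid$target_ct <- base_ct + offset +
      stats::rnorm(nrow(grid), 0, noise_sd)
    grid$ref1_ct <- base_ct
    grid$ref2_ct <- base_ct
    grid[c("sample_id", "transcript_id", "replicate", "target_ct",
           "ref1_ct", "ref2_ct")]
  })
}

#' Write a complete simulated fixture bundle to a directory
#'
#' Emits counts TSV, lengths TSV, sample sheet, annotation map and truth
#' table — every file the pipeline consumes, with known ground truth.
#'
#' @param config A [simulation_config()].
#' @param outdir Target directory (created if needed).
#' @param n_terms,planted_term_effect Passed to [simulate_annotation()].
#' @return Invisibly, the list from [simulate_experiment()] plus the
#'   annotation map.
#' @export
write_simulation_bundle <- function(config = simulation_config(), outdir,
                                    n_terms = 20, planted_term_effect = 10) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_experiment(config)
  ann <- simulate_annotation(sim$truth, n_terms = n_terms,
                             planted_term_effect = planted_term_effect,
                             seed = substream_seed(config$seed, 5))
  write_count_matrix(sim$matrix, file.path(outdir, "counts.tsv"),
                     lengths_path = file.path(outdir, "lengths.tsv"))
  write_sample_sheet(sim$sheet, file.path(outdir, "sample_sheet.tsv"))
  write_annotation_map(ann, file.path(outdir, "annotation.tsv"))
  utils::write.table(sim$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(sim, list(annotation = ann)))
}
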