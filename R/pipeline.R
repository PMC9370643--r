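# End-to-end orchestration: DET calling -> exclusivity -> set algebra ->
# enrichment, with stage TSVs and a plain-text summary report.

#' Run the full differential-transcriptome pipeline
#'
#' Executes, in order: per-comparison DET calling (one genotype contrast per
#' tissue x growth-condition cell), the genotype-exclusivity rule, Venn
#' partitioning of the DET sets, the same-direction stalk/hydroponics
#' intersection per tissue, and term enrichment of each DET set. Every stage
#' writes a TSV into `outdir`, and a `summary.txt` report collects the
#' headline numbers: DET counts split by direction, Venn region counts, the
#' common-pattern totals reported as the disjoint root + shoot sum, per-term
#' enrichment counts, and optional mapping-percentage lines.
#'
#' The pipeline is deterministic: rerunning with the same inputs reproduces
#' every table byte for byte.
#'
#' @param matrix A [count_matrix()].
#' @param sheet A [sample_sheet()] covering the matrix's libraries.
#' @param annotations Optional [annotation_map()] for the enrichment stage.
#' @param outdir Output directory (created if needed).
#' @param alpha,min_abs_log2fc,pseudo Passed to [call_dets()].
#' @param replicate_mode `"POOLED"` or `"PER_PAIR_CONSENSUS"`.
#' @param min_positive_libraries Passed to [call_exclusive()].
#' @param enrichment_alpha,enrichment_adjust Passed to [enrich_terms()].
#' @param mapping_counts Optional data.frame with columns `label`,
#'   `numerator`, `denominator`: summary percentages (e.g. loci mapped per
#'   species) recomputed via [mapping_percentage()] and echoed in the report.
#' @param verbose Emit stage messages (default `TRUE`).
#' @return An object of class `pipeline_report`: list with `dets` (named list
#'   of `det_table`s), `exclusive`, `venn`, `common` (per-tissue directional
#'   sets), `common_totals`, `enrichment` (named list), `summary_lines`,
#'   `outdir`, `params`.
#' @export
run_pipeline <- function(matrix, sheet, annotations = NULL, outdir,
                         alpha = 0.05, min_abs_log2fc = 0, pseudo = 0.25,
                         replicate_mode = "POOLED",
                         min_positive_libraries = 5,
                         enrichment_alpha = 0.05,
                         enrichment_adjust = "NONE",
                         mapping_counts = NULL,
                         verbose = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, ...) {
    if (verbose) message(format(Sys.time(), "[%H:%M:%S] "), stage, ": ", ...)
  }
  stage_try <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop_canedet("stage '", stage, "' failed: ", conditionMessage(e),
                   class = "canedet_stage_error")
    })
  }
  lines <- c("# Differential-transcriptome pipeline summary",
             sprintf("alpha=%g min_abs_log2fc=%g pseudo=%g mode=%s",
                     alpha, min_abs_log2fc, pseudo, replicate_mode),
             sprintf("min_positive_libraries=%d enrichment_alpha=%g adjust=%s",
                     min_positive_libraries, enrichment_alpha,
                     enrichment_adjust),
             "")

  # Stage 1: DET calling, one genotype contrast per tissue/condition cell.
  dets <- stage_try("det", {
    specs <- genotype_comparisons(sheet, replicate_mode)
    out <- list()
    for (nm in names(specs)) {
      say("det", nm)
      out[[nm]] <- call_dets(matrix, specs[[nm]], alpha = alpha,
                             min_abs_log2fc = min_abs_log2fc, pseudo = pseudo,
                             sheet = sheet,
                             min_positive_libraries = min_positive_libraries)
      write_det_table(out[[nm]],
                      file.path(outdir, paste0("det_", nm, ".tsv")))
    }
    out
  })
  lines <- c(lines, "## DET counts by direction (UP_A = high-BNF genotype)")
  for (nm in names(dets)) {
    s <- summary(dets[[nm]])
    lines <- c(lines, sprintf("%s\tUP_A=%d\tUP_B=%d\ttotal=%d",
                              nm, s$n_up_a, s$n_up_b, s$n_up_a + s$n_up_b))
  }

  # Stage 2: genotype-exclusive transcripts.
  exclusive <- stage_try("exclusive", {
    say("exclusive", "applying the >=1 read in ", min_positive_libraries,
        " libraries / never-in-the-other rule")
    excl <- call_exclusive(matrix, sheet,
                           min_positive_libraries = min_positive_libraries)
    utils::write.table(
      data.frame(transcript_id = names(excl), exclusive = unname(excl)),
      file.path(outdir, "exclusive.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    excl
  })
  lines <- c(lines, "",
             sprintf("## Exclusive transcripts: %d (HIGH_BNF %d, LOW_BNF %d)",
                     length(exclusive),
                     sum(exclusive == "EXCLUSIVE_HIGH_BNF"),
                     sum(exclusive == "EXCLUSIVE_LOW_BNF")))

  # Stage 3: set algebra across comparisons.
  venn <- NULL
  common <- list()
  common_totals <- NULL
  if (length(dets) >= 2) {
    venn <- stage_try("intersect", {
      say("intersect", "Venn partition over ", length(dets), " DET sets")
      v <- venn_partition(lapply(dets, det_set), ignore_direction = TRUE)
      write_venn_partition(v, file.path(outdir, "venn.txt"))
      v
    })
    lines <- c(lines, "", "## Venn region counts")
    cnt <- attr(venn, "counts")
    lines <- c(lines, sprintf("%s\t%d", names(venn), cnt))

    common <- stage_try("intersect", {
      out <- list()
      for (tis in unique(sheet$tissue)) {
        stalk <- paste(tis, "STALK", sep = ".")
        hydro <- paste(tis, "HYDROPONIC", sep = ".")
        if (all(c(stalk, hydro) %in% names(dets))) {
          cp <- common_pattern(det_set(dets[[stalk]]), det_set(dets[[hydro]]))
          utils::write.table(
            as.data.frame(cp),
            file.path(outdir, paste0("common_", tolower(tis), ".tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
          out[[tis]] <- cp
        }
      }
      out
    })
    if (length(common)) {
      per_tissue <- vapply(common, nrow, 0L)
      common_totals <- c(per_tissue, total = sum(per_tissue))
      lines <- c(lines, "",
                 "## Common-pattern transcripts (same direction in stalk and hydroponics)",
                 sprintf("%s\t%d", names(per_tissue), per_tissue),
                 sprintf("total\t%d (disjoint sum over tissues)",
                         sum(per_tissue)))
    }
  }

  # Stage 4: term enrichment of each DET set.
  enrichment <- list()
  if (!is.null(annotations)) {
    enrichment <- stage_try("enrich", {
      background <- intersect(transcript_ids(matrix),
                              unique(annotations$transcript_id))
      out <- list()
      for (nm in names(dets)) {
        fg <- intersect(det_set(dets[[nm]])$transcript_id, background)
        if (length(fg) == 0) {
          say("enrich", nm, ": no DETs, skipping")
          lines <- c(lines, "", sprintf("## Enrichment %s: no DETs", nm))
          next
        }
        say("enrich", nm, ": ", length(fg), " foreground transcripts")
        et <- enrich_terms(fg, annotations, background,
                           alpha = enrichment_alpha,
                           adjust = enrichment_adjust)
        write_enrichment_table(
          et, file.path(outdir, paste0("enrichment_", nm, ".tsv")))
        out[[nm]] <- et
      }
      out
    })
    if (length(enrichment)) {
      lines <- c(lines, "", "## Enriched terms per comparison")
      for (nm in names(enrichment)) {
        lines <- c(lines, sprintf("%s\t%d significant of %d tested", nm,
                                  sum(enrichment[[nm]]$significant),
                                  nrow(enrichment[[nm]])))
      }
    }
  }

  # Mapping-percentage arithmetic (summary-table style).
  if (!is.null(mapping_counts)) {
    lines <- c(lines, "", "## Mapping percentages")
    pct <- mapping_percentage(mapping_counts$numerator,
                              mapping_counts$denominator)
    lines <- c(lines, sprintf("%s\t%d/%d\t%.2f%%", mapping_counts$label,
                              mapping_counts$numerator,
                              mapping_counts$denominator, pct))
  }

  writeLines(lines, file.path(outdir, "summary.txt"))
  structure(
    list(dets = dets, exclusive = exclusive, venn = venn, common = common,
         common_totals = common_totals, enrichment = enrichment,
         summary_lines = lines, outdir = outdir,
         params = list(alpha = alpha, min_abs_log2fc = min_abs_log2fc,
                       pseudo = pseudo, replicate_mode = replicate_mode,
                       min_positive_libraries = min_positive_libraries,
                       enrichment_alpha = enrichment_alpha,
                       enrichment_adjust = enrichment_adjust)),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  writeLines(x$summary_lines)
  invisible(x)
}
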