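# Hypergeometric term enrichment of a DET set against an annotated background.

#' Hypergeometric term enrichment with Rich Factor
#'
#' For every term annotated to at least one background transcript, tests
#' whether the foreground (e.g. a DET list) is enriched for the term:
#' `p_raw = P(X >= k)` where `X ~ Hypergeometric(N, K, n)`, `N` = background
#' size, `K` = background transcripts with the term, `n` = foreground size and
#' `k` = foreground transcripts with the term. The Rich Factor is `k / K`.
#' Significance uses raw `p < alpha` by default (the convention of the
#' OmicShare-style analysis this emulates); Benjamini-Hochberg adjustment is
#' available via `adjust = "BH"`.
#'
#' @param foreground Character vector of transcript ids, a subset of
#'   `background`.
#' @param annotations An [annotation_map()].
#' @param background Character vector of background transcript ids; defaults
#'   to all annotated transcripts in the map.
#' @param alpha Significance threshold (default 0.05).
#' @param adjust `"NONE"` (default) or `"BH"`.
#' @return A `data.frame` of class `enrichment_table`, one row per term,
#'   sorted by `p_raw`: columns `term_id`, `namespace`, `k`, `K`, `n`, `N`,
#'   `rich_factor`, `p_raw`, `p_adj`, `significant`.
#' @export
enrich_terms <- function(foreground, annotations, background = NULL,
                         alpha = 0.05, adjust = c("NONE", "BH")) {
  adjust <- match.arg(adjust)
  background <- unique(as.character(background %||% annotations$transcript_id))
  if (length(background) == 0) {
    stop_canedet("background is empty", class = "canedet_empty_input_error")
  }
  foreground <- unique(as.character(foreground))
  stray <- setdiff(foreground, background)
  if (length(stray)) {
    stop_canedet("foreground transcript(s) outside the background: ",
                 paste(utils::head(stray, 10), collapse = ", "),
                 if (length(stray) > 10) ", ..." else "",
                 class = "canedet_containment_error")
  }

  ann <- annotations[annotations$transcript_id %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(foreground)
  terms <- unique(ann[c("term_id", "namespace")])
  if (nrow(terms) == 0) {
    out <- data.frame(term_id = character(), namespace = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), rich_factor = numeric(),
                      p_raw = numeric(), p_adj = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
    class(out) <- c("enrichment_table", "data.frame")
    return(out)
  }
  key <- paste(ann$term_id, ann$namespace, sep = "\r")
  K <- as.vector(table(key)[paste(terms$term_id, terms$namespace, sep = "\r")])
  fg_ann <- ann[ann$transcript_id %in% foreground, , drop = FALSE]
  fg_key <- paste(fg_ann$term_id, fg_ann$namespace, sep = "\r")
  k <- as.vector(table(factor(fg_key, levels = paste(terms$term_id,
                                                     terms$namespace,
                                                     sep = "\r"))))
  p_raw <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_adj <- if (adjust == "BH") stats::p.adjust(p_raw, "BH") else rep(NA_real_, length(p_raw))
  significant <- if (adjust == "BH") p_adj < alpha else p_raw < alpha

  out <- data.frame(term_id = terms$term_id, namespace = terms$namespace,
                    k = k, K = K, n = n, N = N,
                    rich_factor = rich_factor(k, K),
                    p_raw = p_raw, p_adj = p_adj, significant = significant,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_raw, out$term_id), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Rich Factor
#'
#' Foreground transcripts annotated to a category divided by background
#' transcripts annotated to that category: `k / K`.
#'
#' @param k Foreground count(s), `0 <= k <= K`.
#' @param K Background count(s), `>= 1`.
#' @return Ratio(s) in `[0, 1]`.
#' @export
rich_factor <- function(k, K) {
  if (any(K < 1)) stop_canedet("K must be >= 1", class = "canedet_domain_error")
  if (any(k < 0 | k > K)) {
    stop_canedet("k must satisfy 0 <= k <= K", class = "canedet_domain_error")
  }
  k / K
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat("enrichment_table:", nrow(x), "terms,", sum(x$significant),
      "significant\n")
  print(utils::head(as.data.frame(unclass(x)), 10), ...)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Write an enrichment table to TSV
#' @param x An `enrichment_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(x, path) {
  utils::write.table(as.data.frame(unclass(x)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
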