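# Internal helpers shared across the package.

#' @keywords internal
"_PACKAGE"

# Half-up rounding (R's round() is round-half-even). A one-ulp relative nudge
# guards against values like 2.5 being represented as 2.4999...
round_half_up <- function(x, digits = 0) {
  scaled <- x * 10^digits
  scaled <- scaled * (1 + 8 * .Machine$double.eps)
  floor(scaled + 0.5) / 10^digits
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a reproducible substream seed from a master seed; keeps the result a
# valid 32-bit integer whatever the master is.
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset * 1009) %% .Machine$integer.max)
}

stop_canedet <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "canedet_error")))
}

is_count <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == floor(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
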