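#' @keywords internal
"_PACKAGE"

SENTIMENT_CLASSES <- c("negative", "neutral", "positive")

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. All randomness inside the package goes through this.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic fan-out of one pipeline seed into per-stage seeds.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
stage_seed <- function(seed, stage) {
  (as.double(seed) * 48271 + stage * 1000003) %% 2147483647
}

#' Round half away from zero
#'
#' Display rounding used for percent metrics: 82.545 becomes 82.55 rather
#' than the banker's-rounding 82.54. Raw full-precision values are kept
#' internally; this is applied only when formatting.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half up (away from zero).
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

assert_class_labels <- function(x, what = "label") {
  bad <- setdiff(unique(as.character(x)), SENTIMENT_CLASSES)
  if (length(bad) > 0) {
    stop(sprintf("unknown %s(s): %s (expected %s)", what,
                 paste(bad, collapse = ", "),
                 paste(SENTIMENT_CLASSES, collapse = "/")), call. = FALSE)
  }
  invisible(x)
}
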