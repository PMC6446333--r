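# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so simulation functions never perturb the session stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

chromsub_error <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "chromsub_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  ))
}

config_error <- function(field, msg) {
  chromsub_error(sprintf("invalid configuration: field '%s' %s", field, msg),
                 "chromsub_config_error")
}

lookup_error <- function(what, value) {
  chromsub_error(sprintf("unknown %s: '%s'", what, value),
                 "chromsub_lookup_error")
}

consistency_error <- function(msg) {
  chromsub_error(msg, "chromsub_consistency_error")
}

input_error <- function(msg) {
  chromsub_error(msg, "chromsub_input_error")
}

#' Render a missing-call percentage from integer counts
#'
#' Formats `100 * n_missing / n_mapped` with one decimal place using
#' round-half-even, computed in exact integer arithmetic so printed count
#' pairs round-trip exactly (e.g. 1535/2601 -> "59.0%", 204/2590 -> "7.9%").
#'
#' @param n_missing integer vector of missing-call counts.
#' @param n_mapped integer vector of mapped-marker counts (> 0).
#' @param percent_sign append "%" (default TRUE).
#' @return character vector like "59.0%".
#' @examples
#' percent_from_counts(1535, 2601)
#' percent_from_counts(c(35, 212), c(2632, 2542))
#' @export
percent_from_counts <- function(n_missing, n_mapped, percent_sign = TRUE) {
  if (any(n_mapped < 1)) input_error("n_mapped must be >= 1")
  if (any(n_missing < 0) || any(n_missing > n_mapped))
    input_error("n_missing must lie in [0, n_mapped]")
  # value in tenths of a percent: round-half-even of 1000*n/d
  num <- 1000 * as.numeric(n_missing)
  den <- as.numeric(n_mapped)
  q <- num %/% den
  r <- num %% den
  up <- (2 * r > den) | (2 * r == den & q %% 2 == 1)
  tenths <- q + up
  out <- sprintf("%.1f", tenths / 10)
  if (percent_sign) out <- paste0(out, "%")
  out
}

#' Render a ratio as a one-decimal percentage
#'
#' Floating-point analogue of [percent_from_counts()] for quantities that
#' are not count pairs (e.g. a rate computed across seeds).
#'
#' @param x numeric vector of fractions in \[0, 1\].
#' @param percent_sign append "%" (default TRUE).
#' @return character vector.
#' @export
percent_from_ratio <- function(x, percent_sign = TRUE) {
  out <- sprintf("%.1f", round(x * 1000) / 10)  # round() is half-even
  if (percent_sign) out <- paste0(out, "%")
  out
}

# Coordinate conventions, centralized:
# marker positions are 1-based inclusive; windows are 0-based half-open
# [start, end). A marker at position p belongs to a window iff
# start < p <= end.
marker_in_window <- function(pos, start, end) {
  pos > start & pos <= end
}
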