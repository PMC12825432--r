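# internal helpers shared across modules

# round half away from zero (round() uses banker's rounding, which would
# display 0.5-boundary percentages unpredictably)
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stop_ic <- function(fmt, ..., class = "icscreen_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

#' Format a percentage for display
#'
#' Computes `100 * numerator / denominator` and rounds half away from zero to
#' the requested number of decimals, the convention used throughout the
#' screen's reports. The unrounded fraction is never used for classification
#' decisions; this is display only.
#'
#' @param numerator,denominator Non-negative counts; `denominator` must be
#'   positive.
#' @param decimals Number of decimal places to keep (default 1).
#' @return A string such as `"27.2%"`.
#' @examples
#' percent_display(12, 151)   # "7.9%"
#' percent_display(6, 25, 0)  # "24%"
#' @export
percent_display <- function(numerator, denominator, decimals = 1) {
  if (!is.numeric(denominator) || length(denominator) != 1L ||
      is.na(denominator) || denominator <= 0) {
    stop_ic("percent_display: denominator must be a single positive number")
  }
  if (!is.numeric(numerator) || length(numerator) != 1L || is.na(numerator)) {
    stop_ic("percent_display: numerator must be a single number")
  }
  value <- round_half_away(100 * numerator / denominator, decimals)
  sprintf("%.*f%%", decimals, value)
}

# percentage value (numeric, display-rounded); shared by reports
percent_value <- function(numerator, denominator, decimals = 1) {
  round_half_away(100 * numerator / denominator, decimals)
}

# flag percentages whose display depends on the rounding rule: truncation vs
# half-away-from-zero disagree. Reports log these instead of silently picking
# one (printed tables in the literature mix both conventions).
rounding_sensitive <- function(numerator, denominator, decimals = 1) {
  m <- 10^decimals
  x <- 100 * numerator / denominator
  trunc(x * m) / m != round_half_away(x, decimals)
}
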