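# Shared numeric/formatting helpers.

#' Column percentage at two decimals
#'
#' Percentage of `count` out of `total`, rounded half-away-from-zero to two
#' decimal places -- the rounding convention used throughout the descriptive
#' tables (e.g. 575/15910 prints as 3.61, 297/575 as 51.65).
#'
#' @param count Non-negative integer count (vectorised).
#' @param total Positive integer denominator (scalar or same length).
#' @return Numeric percentage(s) on the 0-100 scale, two decimals.
#' @examples
#' percent(575, 15910)  # 3.61
#' percent(297, 575)    # 51.65
#' @export
percent <- function(count, total) {
  if (any(is.na(total)) || any(total < 1)) {
    stop("`total` must be a positive integer", call. = FALSE)
  }
  if (any(!is.na(count) & (count < 0 | count > total))) {
    stop("`count` must satisfy 0 <= count <= total", call. = FALSE)
  }
  round_half_away(100 * count / total, 2L)
}

# round-half-away-from-zero at `digits` decimals; base round() is banker's
# rounding and would give 2.4 for round(2.45, 1). The 1e-9 guard absorbs
# binary representation error in ratios of integers.
round_half_away <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Render a p-value the way the published tables do
#'
#' Three decimals, with a display floor of `"<0.001"` and `"NE"` (not
#' evaluated) for missing values.
#'
#' @param p Numeric vector of p-values (NA allowed).
#' @return Character vector.
#' @examples
#' format_p(c(0.0004, 0.037, NA))
#' @export
format_p <- function(p) {
  out <- ifelse(is.na(p), "NE",
    ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
  )
  as.character(out)
}

# deterministic seed stream derived from a base seed (kept below 2^31)
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1103L + i * 7919) %% 2147483647)
}
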