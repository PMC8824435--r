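# Disproportionality signal mining over drug-event combinations (DECs):
# ROR, PRR and the MHRA criterion (report count + Yates-corrected
# chi-square), with the standard 2 x 2 orientation
#
#           suspect ADR   other ADRs
#   drug        a             b
#   others      c             d
#
# so that ROR = ad/bc and PRR = [a/(a+b)] / [c/(c+d)] are simultaneously
# consistent.

#' Build per-DEC 2 x 2 contingency tables
#'
#' One table per distinct (drug, ADR term) pair present in the database.
#' Each report contributes exactly one pair, so for every DEC the four
#' cells partition the full report set: a + b + c + d = n.
#'
#' @param reports Filtered report tibble.
#' @return Tibble with columns `drug_name`, `adr_term`, `a`, `b`, `c`, `d`.
#' @export
build_dec_tables <- function(reports) {
  n <- nrow(reports)
  dec <- dplyr::count(reports, .data$drug_name, .data$adr_term, name = "a")
  drug_tot <- dplyr::count(reports, .data$drug_name, name = "n_drug")
  event_tot <- dplyr::count(reports, .data$adr_term, name = "n_event")
  dec |>
    dplyr::left_join(drug_tot, by = "drug_name") |>
    dplyr::left_join(event_tot, by = "adr_term") |>
    dplyr::mutate(b = .data$n_drug - .data$a,
                  c = .data$n_event - .data$a,
                  d = n - .data$a - .data$b - .data$c) |>
    dplyr::select("drug_name", "adr_term", "a", "b", "c", "d")
}

#' Reporting odds ratio with 95 percent CI
#'
#' ROR = ad/bc with Woolf-type CI
#' exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)). Undefined (all-`NA`)
#' whenever any cell is zero: a zero denominator cell makes the ratio
#' degenerate and a zero numerator cell makes the CI incomputable; such
#' DECs cannot pass the signal criteria in any case.
#'
#' @param a,b,c,d Cell counts (vectorised).
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble: `ror`, `ci_low`, `ci_high`.
#' @export
ror <- function(a, b, c, d, conf_level = 0.95) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  val <- ifelse(ok, (a * d) / (b * c), NA_real_)
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  tibble::tibble(ror = val,
                 ci_low = exp(log(val) - z * se),
                 ci_high = exp(log(val) + z * se))
}

#' Proportional reporting ratio with 95 percent CI
#'
#' PRR = [a/(a+b)] / [c/(c+d)]. By default the CI uses the same standard
#' error form as the ROR, sqrt(1/a + 1/b + 1/c + 1/d) (`prr_se =
#' "printed"`); the textbook PRR standard error
#' sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)) is available with `prr_se =
#' "textbook"`. Undefined when a, b, c or d is zero.
#'
#' @param a,b,c,d Cell counts (vectorised).
#' @param conf_level Confidence level (default 0.95).
#' @param prr_se `"printed"` or `"textbook"` standard-error form.
#' @return Tibble: `prr`, `ci_low`, `ci_high`.
#' @export
prr <- function(a, b, c, d, conf_level = 0.95,
                prr_se = c("printed", "textbook")) {
  prr_se <- match.arg(prr_se)
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  val <- ifelse(ok, (a / (a + b)) / (c / (c + d)), NA_real_)
  se <- if (prr_se == "printed") {
    ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  } else {
    ifelse(ok, sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d)), NA_real_)
  }
  tibble::tibble(prr = val,
                 ci_low = exp(log(val) - z * se),
                 ci_high = exp(log(val) + z * se))
}

#' Yates-corrected chi-square for the MHRA criterion
#'
#' The standard continuity-corrected 2 x 2 statistic
#' n * (max(0, |ad - bc| - n/2))^2 / [(a+b)(c+d)(a+c)(b+d)], clamped to zero
#' when |ad - bc| <= n/2 so balanced tables never acquire a spurious
#' positive value. Undefined (`NA`) when any margin is zero.
#'
#' @param a,b,c,d Cell counts (vectorised).
#' @return Numeric chi-square value(s), >= 0.
#' @export
mhra_chi2 <- function(a, b, c, d) {
  # counts may arrive as integers; the denominator overflows integer range
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  margins_ok <- (a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0
  num <- pmax(0, abs(a * d - b * c) - n / 2)^2 * n
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  ifelse(margins_ok, num / den, NA_real_)
}

#' Evaluate the signal criteria for DEC tables
#'
#' Criteria per method: ROR -- a >= 3 and lower 95 percent CI limit > 1;
#' PRR -- a >= 3, PRR >= 2 and lower 95 percent CI limit > 1; MHRA --
#' a >= 3 and Yates chi-square >= 4. An undefined metric fails its
#' criterion. The combined `signal` flag is the intersection of the three
#' by default; `rule = "union"` flags a DEC passing any method.
#'
#' @param dec_tables Tibble from [build_dec_tables()] (columns `drug_name`,
#'   `adr_term`, `a`, `b`, `c`, `d`).
#' @param rule `"intersection"` (default) or `"union"`.
#' @param prr_se Passed to [prr()].
#' @return A `signal_metrics` tibble: the input cells plus `ror`,
#'   `ror_ci_low`, `ror_ci_high`, `prr`, `prr_ci_low`, `prr_ci_high`,
#'   `chi2_yates`, `ror_pass`, `prr_pass`, `mhra_pass`, `signal`.
#' @export
evaluate_signal <- function(dec_tables, rule = c("intersection", "union"),
                            prr_se = c("printed", "textbook")) {
  rule <- match.arg(rule)
  prr_se <- match.arg(prr_se)
  a <- dec_tables$a; b <- dec_tables$b; c <- dec_tables$c; d <- dec_tables$d
  r <- ror(a, b, c, d)
  p <- prr(a, b, c, d, prr_se = prr_se)
  x2 <- mhra_chi2(a, b, c, d)
  ror_pass <- !is.na(r$ci_low) & a >= 3 & r$ci_low > 1
  prr_pass <- !is.na(p$ci_low) & a >= 3 & p$prr >= 2 & p$ci_low > 1
  mhra_pass <- !is.na(x2) & a >= 3 & x2 >= 4
  signal <- if (rule == "intersection") {
    ror_pass & prr_pass & mhra_pass
  } else {
    ror_pass | prr_pass | mhra_pass
  }
  out <- tibble::tibble(
    drug_name = dec_tables$drug_name, adr_term = dec_tables$adr_term,
    a = a, b = b, c = c, d = d,
    ror = r$ror, ror_ci_low = r$ci_low, ror_ci_high = r$ci_high,
    prr = p$prr, prr_ci_low = p$ci_low, prr_ci_high = p$ci_high,
    chi2_yates = x2,
    ror_pass = ror_pass, prr_pass = prr_pass, mhra_pass = mhra_pass,
    signal = signal
  )
  structure(out, class = c("signal_metrics", class(out)), rule = rule)
}

#' Ranked signal table
#'
#' Keeps only flagged DECs, sorted by Yates chi-square descending, with the
#' point estimates and lower CI limits rounded to two decimals -- the usual
#' published layout for an SRS signal table.
#'
#' @param metrics `signal_metrics` tibble from [evaluate_signal()].
#' @return Tibble: `drug_name`, `adr_term`, `ror`, `ror_ci_low`, `prr`,
#'   `prr_ci_low`, `chi2_yates`.
#' @export
rank_signals <- function(metrics) {
  out <- metrics[metrics$signal, , drop = FALSE]
  out <- out[order(-out$chi2_yates, out$drug_name, out$adr_term), ]
  tibble::tibble(
    drug_name = out$drug_name, adr_term = out$adr_term,
    ror = round_half_away(out$ror, 2L),
    ror_ci_low = round_half_away(out$ror_ci_low, 2L),
    prr = round_half_away(out$prr, 2L),
    prr_ci_low = round_half_away(out$prr_ci_low, 2L),
    chi2_yates = round_half_away(out$chi2_yates, 2L)
  )
}
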