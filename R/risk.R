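# Risk modelling: crude odds ratios, binary logistic regression for ADR
# severity/impact, and Mantel-Haenszel stratified odds ratios.

#' Crude odds ratio with Woolf confidence interval
#'
#' OR = ad/bc with CI exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)). When
#' exactly one cell is zero, the Haldane-Anscombe correction (+0.5 to all
#' four cells) is applied and flagged; with two zero cells in the same row
#' or column the OR is undefined and flagged.
#'
#' @param table 2 x 2 matrix `rbind(c(a, b), c(c, d))`, or a length-4 vector
#'   `c(a, b, c, d)`.
#' @param conf_level Confidence level (default 0.95).
#' @return List: `or`, `ci_low`, `ci_high`, `haldane` (correction applied?),
#'   `defined`.
#' @examples
#' crude_or(c(10, 20, 30, 40))  # OR 0.667, CI (0.273, 1.631)
#' @export
crude_or <- function(table, conf_level = 0.95) {
  cells <- as.numeric(t(as.matrix(table)))
  if (length(cells) != 4 || any(cells < 0) || any(is.na(cells))) {
    stop("`table` must hold four non-negative counts a, b, c, d", call. = FALSE)
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  n_zero <- sum(cells == 0)
  undefined <- (a == 0 && b == 0) || (c == 0 && d == 0) ||
               (a == 0 && c == 0) || (b == 0 && d == 0)
  if (undefined || n_zero >= 2) {
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                haldane = FALSE, defined = FALSE))
  }
  haldane <- n_zero == 1
  if (haldane) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se),
       haldane = haldane, defined = TRUE)
}

# reference levels matching the published model structure
LOGISTIC_TERMS <- list(
  drug_class       = list(levels = c("non_mab", "mab")),
  age_group        = list(levels = c("18-34", "0-5", "6-17", "35-59", "60-79", ">=80")),
  sex              = list(levels = c("male", "female")),
  disease_type     = list(levels = c("single", "multiple")),
  polypharmacy     = list(levels = c("non_polypharmacy", "polypharmacy")),
  past_adr_history = list(levels = c("no", "yes"))
)

#' Binary logistic regression for ADR severity or impact
#'
#' Maximum-likelihood logistic fit (via iteratively reweighted least
#' squares) of a binary ADR outcome on categorical report covariates.
#' Outcomes are coded 1 for `"serious"` (severity model) and `"effect"`
#' (impact model), so negative coefficients are protective. Reference
#' levels: non-mAb, male, age 18-34, single disease, non-polypharmacy, no
#' past ADR history. Reports with a missing or unknown value in the outcome
#' or any requested term are dropped. A fit where any coefficient exceeds 15
#' in absolute value is flagged as non-converged (quasi-separation).
#'
#' @param reports Report tibble.
#' @param outcome `"severity"` or `"impact"`.
#' @param terms Character vector of covariates (default: all published
#'   model terms).
#' @param weights Optional non-negative case weights (e.g. grouped counts).
#' @param conf_level Confidence level for the Wald ORs (default 0.95).
#' @return A `regression_result`: tibble with columns `term`, `beta`, `se`,
#'   `or`, `ci_low`, `ci_high`, plus attributes `converged`, `iterations`,
#'   `log_lik`, `n`.
#' @export
fit_logistic <- function(reports, outcome = c("severity", "impact"),
                         terms = names(LOGISTIC_TERMS), weights = NULL,
                         conf_level = 0.95) {
  outcome <- match.arg(outcome)
  bad <- setdiff(terms, names(LOGISTIC_TERMS))
  if (length(bad) > 0) stop("unknown model term(s): ", paste(bad, collapse = ", "),
                            call. = FALSE)
  y <- if (outcome == "severity") {
    as.integer(reports$severity == "serious")
  } else {
    as.integer(dichotomize_impact(reports$impact) == "effect")
  }
  mf <- data.frame(.y = y)
  for (tm in terms) {
    v <- derived_var(reports, tm)
    v[v == "unknown"] <- NA_character_
    mf[[tm]] <- factor(v, levels = LOGISTIC_TERMS[[tm]]$levels)
  }
  mf$.w <- if (is.null(weights)) 1 else as.numeric(weights)
  mf <- mf[stats::complete.cases(mf) & mf$.w > 0, ]
  if (length(unique(mf$.y)) < 2) {
    stop("outcome does not vary: logistic model cannot be fitted", call. = FALSE)
  }
  form <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  fit <- stats::glm(form, family = stats::binomial(), data = mf, weights = mf$.w)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  separated <- any(abs(beta) > 15, na.rm = TRUE)
  converged <- fit$converged && !separated
  if (separated) {
    warning("possible separation: a coefficient exceeds 15 in absolute value",
            call. = FALSE)
  }
  out <- tibble::tibble(
    term = names(beta), beta = unname(beta), se = unname(se),
    or = exp(unname(beta)),
    ci_low = exp(unname(beta) - z * unname(se)),
    ci_high = exp(unname(beta) + z * unname(se))
  )
  structure(out, class = c("regression_result", class(out)),
            outcome = outcome, converged = converged,
            iterations = fit$iter, log_lik = as.numeric(stats::logLik(fit)),
            n = nrow(mf))
}

#' @export
print.regression_result <- function(x, ...) {
  cat("Logistic model for", attr(x, "outcome"),
      sprintf("(n = %d, %s)\n", attr(x, "n"),
              if (attr(x, "converged")) "converged" else "NOT converged"))
  NextMethod()
}

#' Mantel-Haenszel pooled odds ratio across strata
#'
#' OR_MH = sum(a_i d_i / n_i) / sum(b_i c_i / n_i), with the
#' Robins-Breslow-Greenland variance for ln OR_MH. Strata with zero total
#' are skipped (they contribute nothing).
#'
#' @param strata List of 2 x 2 count matrices (rows: exposed/unexposed,
#'   columns: outcome yes/no).
#' @param conf_level Confidence level (default 0.95).
#' @return List: `or`, `ci_low`, `ci_high`, `n_strata_used`, `defined`.
#' @export
mh_pooled_or <- function(strata, conf_level = 0.95) {
  if (length(strata) < 1) stop("at least one stratum required", call. = FALSE)
  mats <- lapply(strata, function(s) matrix(as.numeric(t(as.matrix(s))), 2, 2, byrow = TRUE))
  ns <- vapply(mats, sum, numeric(1))
  mats <- mats[ns > 0]
  if (length(mats) == 0) {
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                n_strata_used = 0L, defined = FALSE))
  }
  a <- vapply(mats, function(m) m[1, 1], numeric(1))
  b <- vapply(mats, function(m) m[1, 2], numeric(1))
  c <- vapply(mats, function(m) m[2, 1], numeric(1))
  d <- vapply(mats, function(m) m[2, 2], numeric(1))
  n <- a + b + c + d
  R <- a * d / n
  S <- b * c / n
  if (sum(R) == 0 || sum(S) == 0) {
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                n_strata_used = length(mats), defined = FALSE))
  }
  or <- sum(R) / sum(S)
  P <- (a + d) / n
  Q <- (b + c) / n
  var_ln <- sum(P * R) / (2 * sum(R)^2) +
            sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
            sum(Q * S) / (2 * sum(S)^2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = or,
       ci_low = exp(log(or) - z * sqrt(var_ln)),
       ci_high = exp(log(or) + z * sqrt(var_ln)),
       n_strata_used = length(mats), defined = TRUE)
}

#' Stratified mAb effect on the dichotomised impact outcome
#'
#' Within each level of `stratify_var`, builds the 2 x 2 table of drug class
#' (mAb vs non-mAb) against the dichotomised impact outcome (effect vs no
#' effect), computes the crude OR with Woolf CI, and pools the strata with
#' the Mantel-Haenszel estimator. ORs below 1 mean mAb reports were less
#' likely to record an impact on the primary disease in that stratum.
#'
#' @param reports Report tibble.
#' @param stratify_var One of `"sex"`, `"age_group"`, `"disease_type"`,
#'   `"polypharmacy"`, `"past_adr_history"`.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `strata` (tibble: level, a, b, c, d, or, ci_low,
#'   ci_high, defined) and `pooled` (the [mh_pooled_or()] result).
#' @export
stratified_mab_effect <- function(reports,
                                  stratify_var = c("sex", "age_group",
                                                   "disease_type", "polypharmacy",
                                                   "past_adr_history"),
                                  conf_level = 0.95) {
  stratify_var <- match.arg(stratify_var)
  sv <- derived_var(reports, stratify_var)
  sv[sv == "unknown"] <- NA_character_
  y <- dichotomize_impact(reports$impact)
  keep <- !is.na(sv) & !is.na(y) & !is.na(reports$drug_class)
  sv <- sv[keep]; y <- y[keep]; cls <- reports$drug_class[keep]

  lvls <- var_levels(sv)
  rows <- list(); mats <- list()
  for (lv in lvls) {
    in_lv <- sv == lv
    a <- sum(in_lv & cls == "mab" & y == "effect")
    b <- sum(in_lv & cls == "mab" & y == "no_effect")
    c <- sum(in_lv & cls == "non_mab" & y == "effect")
    d <- sum(in_lv & cls == "non_mab" & y == "no_effect")
    est <- crude_or(c(a, b, c, d), conf_level = conf_level)
    rows[[lv]] <- tibble::tibble(level = lv, a = a, b = b, c = c, d = d,
                                 or = est$or, ci_low = est$ci_low,
                                 ci_high = est$ci_high, defined = est$defined)
    mats[[lv]] <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  }
  list(strata = dplyr::bind_rows(rows),
       pooled = mh_pooled_or(mats, conf_level = conf_level))
}
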