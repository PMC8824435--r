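# Crude ORs, logistic models and Mantel-Haenszel pooling.

test_that("crude OR matches the Woolf formula", {
  est <- crude_or(c(10, 20, 30, 40))
  expect_equal(est$or, 2 / 3, tolerance = 1e-9)
  expect_equal(c(est$ci_low, est$ci_high),
               woolf_ci_oracle(10, 20, 30, 40), tolerance = 1e-9)
  # severity 2x2 of the reference counts
  expect_equal(crude_or(c(174, 401, 5285, 10050))$or, 0.8251, tolerance = 1e-4)
  for (k in c(1, 3, 10)) expect_equal(crude_or(c(k, k, k, k))$or, 1)
})

test_that("zero cells trigger the Haldane correction or an undefined flag", {
  one_zero <- crude_or(c(0, 10, 5, 20))
  expect_true(one_zero$haldane)
  expect_equal(one_zero$or, (0.5 * 20.5) / (10.5 * 5.5), tolerance = 1e-12)
  two_zero <- crude_or(c(0, 0, 5, 20))
  expect_false(two_zero$defined)
  expect_true(is.na(two_zero$or))
})

test_that("single-binary-predictor logistic equals the crude log odds ratio", {
  set.seed(5)
  for (i in 1:20) {
    cells <- sample(5:200, 4)  # a, b, c, d: mab/effect orientation
    grouped <- make_reports(
      4,
      drug_class = c("mab", "mab", "non_mab", "non_mab"),
      severity = c("serious", "non_serious", "serious", "non_serious")
    )
    fit <- fit_logistic(grouped, outcome = "severity", terms = "drug_class",
                        weights = cells)
    beta_mab <- fit$beta[fit$term == "drug_classmab"]
    expect_equal(beta_mab, log(cells[1] * cells[4] / (cells[2] * cells[3])),
                 tolerance = 1e-6)
  }
})

test_that("a non-varying outcome is rejected", {
  allser <- make_reports(10, severity = "serious")
  expect_error(fit_logistic(allser, outcome = "severity", terms = "drug_class"),
               "outcome does not vary")
})

test_that("reference levels carry no coefficient and CIs bracket the OR", {
  cfg <- sim_config(n_reports = 4000, seed = 21)
  db <- generate_reports(cfg)
  fit <- fit_logistic(db, outcome = "impact")
  ref_terms <- c("drug_classnon_mab", "sexmale", "age_group18-34",
                 "disease_typesingle", "polypharmacynon_polypharmacy",
                 "past_adr_historyno")
  expect_false(any(ref_terms %in% fit$term))
  expect_true(all(fit$ci_low <= fit$or & fit$or <= fit$ci_high))
  expect_true(attr(fit, "converged"))
})

test_that("MH pooled OR matches hand-computed sums and the one-stratum identity", {
  s1 <- matrix(c(10, 20, 30, 40), 2, 2, byrow = TRUE)
  expect_equal(mh_pooled_or(list(s1))$or, crude_or(c(10, 20, 30, 40))$or)
  expect_equal(mh_pooled_or(list(s1, s1))$or, 2 / 3, tolerance = 1e-12)

  s2a <- matrix(c(10, 10, 5, 20), 2, 2, byrow = TRUE)
  s2b <- matrix(c(2, 8, 4, 16), 2, 2, byrow = TRUE)
  expect_equal(mh_pooled_or(list(s2a, s2b))$or,
               (200 / 45 + 32 / 30) / (50 / 45 + 32 / 30), tolerance = 1e-9)
  expect_equal(mh_pooled_or(list(s2a, s2b))$or, 2.530612, tolerance = 1e-6)

  # an empty stratum is neutral
  s0 <- matrix(0, 2, 2)
  expect_equal(mh_pooled_or(list(s2a, s0, s2b))$or,
               mh_pooled_or(list(s2a, s2b))$or)
})

test_that("MH estimate and interval agree with the stats cross-check", {
  s2a <- matrix(c(10, 10, 5, 20), 2, 2, byrow = TRUE)
  s2b <- matrix(c(2, 8, 4, 16), 2, 2, byrow = TRUE)
  arr <- array(c(s2a, s2b), dim = c(2, 2, 2))
  ref <- stats::mantelhaen.test(arr, exact = FALSE, correct = FALSE)
  got <- mh_pooled_or(list(s2a, s2b))
  expect_equal(got$or, unname(ref$estimate), tolerance = 1e-9)
  expect_equal(c(got$ci_low, got$ci_high), as.numeric(ref$conf.int),
               tolerance = 1e-6)
})

test_that("pooled MH OR lies between the extreme stratum ORs", {
  set.seed(9)
  for (i in 1:30) {
    strata <- lapply(1:3, function(j) matrix(sample(1:50, 4), 2, 2))
    ors <- vapply(strata, function(s) (s[1, 1] * s[2, 2]) / (s[1, 2] * s[2, 1]),
                  numeric(1))
    pooled <- mh_pooled_or(strata)$or
    expect_gte(pooled, min(ors) - 1e-12)
    expect_lte(pooled, max(ors) + 1e-12)
  }
})

test_that("widening the confidence level never narrows an interval", {
  est95 <- crude_or(c(12, 34, 56, 78), conf_level = 0.95)
  est99 <- crude_or(c(12, 34, 56, 78), conf_level = 0.99)
  expect_lte(est99$ci_low, est95$ci_low)
  expect_gte(est99$ci_high, est95$ci_high)

  s <- list(matrix(c(10, 10, 5, 20), 2, 2, byrow = TRUE))
  expect_lte(mh_pooled_or(s, conf_level = 0.99)$ci_low,
             mh_pooled_or(s, conf_level = 0.95)$ci_low)

  cfg <- sim_config(n_reports = 3000, seed = 31)
  db <- generate_reports(cfg)
  f95 <- fit_logistic(db, outcome = "severity", terms = "drug_class")
  f99 <- fit_logistic(db, outcome = "severity", terms = "drug_class",
                      conf_level = 0.99)
  expect_true(all(f99$ci_low <= f95$ci_low & f99$ci_high >= f95$ci_high))
})

test_that("stratified mAb effect recovers stratum-specific generative ORs", {
  # stratum-specific effect: protective in females only
  base <- sim_config(n_reports = 30000, seed = 41)
  om <- base$outcome_model
  om$impact <- c(intercept = qlogis(0.25), mab = 0, female = 0,
                 multiple = 0, poly = 0, history = 0)
  # generate males (OR 1) and females (OR 0.5) separately, then combine
  cfg_m <- sim_config(n_reports = 15000, seed = 42,
                      marginals = list(sex = c(male = 1, female = 0, unknown = 0)),
                      outcome_model = om)
  om_f <- om
  om_f$impact[["mab"]] <- log(0.5)
  cfg_f <- sim_config(n_reports = 15000, seed = 43,
                      marginals = list(sex = c(male = 0, female = 1, unknown = 0)),
                      outcome_model = om_f)
  db <- dplyr::bind_rows(generate_reports(cfg_m), generate_reports(cfg_f))
  res <- stratified_mab_effect(db, "sex")
  or_f <- res$strata$or[res$strata$level == "female"]
  or_m <- res$strata$or[res$strata$level == "male"]
  # generative truths within sampling tolerance at ~500 mAb reports/stratum
  expect_lt(abs(log(or_f) - log(0.5)), 3 * 0.18)
  expect_lt(abs(log(or_m)), 3 * 0.15)
  # pooled MH between the stratum estimates
  expect_gte(res$pooled$or, min(or_f, or_m))
  expect_lte(res$pooled$or, max(or_f, or_m))
})

test_that("absent exposure variation yields undefined stratum ORs", {
  rp <- make_reports(40, impact = rep(c("worse", "no_effect"), 20))
  res <- stratified_mab_effect(rp, "sex")
  expect_true(all(!res$strata$defined))
  expect_false(res$pooled$defined)
})
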