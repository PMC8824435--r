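# Percentages, chi-square / Fisher tests and the descriptive tables.

test_that("percent rounds half away from zero at two decimals", {
  expect_equal(percent(575, 15910), 3.61)   # 3.6141...
  expect_equal(percent(297, 575), 51.65)    # 51.652...
  expect_equal(percent(508, 575), 88.35)    # 88.348 rounds up
  expect_equal(percent(80, 575), 13.91)     # 13.913
  expect_equal(percent(0, 100), 0)
  expect_error(percent(1, 0), "positive")
  expect_error(percent(5, 4), "count")
})

test_that("percent is scale-free in the counts", {
  set.seed(1)
  for (i in 1:50) {
    n <- sample(2:500, 1)
    a <- sample.int(n, 1)
    k <- sample(1:9, 1)
    expect_identical(percent(k * a, k * n), percent(a, n))
  }
})

test_that("pearson chi-square matches brute-force arithmetic on random tables", {
  set.seed(7)
  for (i in 1:200) {
    dims <- sample(2:4, 2, replace = TRUE)
    tab <- matrix(sample(1:80, prod(dims), replace = TRUE), dims[1], dims[2])
    got <- pearson_chi2_test(tab)
    expect_equal(got$statistic, chi2_oracle(tab), tolerance = 1e-10)
    expect_equal(got$df, (dims[1] - 1) * (dims[2] - 1))
    expect_equal(got$p_value, pchisq(chi2_oracle(tab), got$df, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("proportional rows give X2 = 0 and p = 1, and corrections are absent", {
  tab <- rbind(c(10, 20), c(30, 60))
  got <- pearson_chi2_test(tab)
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 1)
  # the severity 2x2 of the reference data is only significant WITHOUT the
  # continuity correction
  sev <- rbind(c(174, 5285), c(401, 10050))
  got <- pearson_chi2_test(sev)
  expect_equal(got$statistic, 4.3433, tolerance = 1e-4)
  expect_lt(got$p_value, 0.05)
})

test_that("fisher exact equals full hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(rbind(c(3, 1), c(1, 3))), 34 / 70,
               tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(rbind(c(0, 5), c(5, 0))), 2 / 252,
               tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(rbind(c(4, 6), c(4, 6))), 1)
  set.seed(11)
  for (i in 1:100) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2, 2)
    if (sum(tab) == 0 || sum(tab) > 60) next
    expect_equal(fisher_exact_2x2(tab), fisher_oracle(tab), tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(matrix(1:6, 2, 3)), "2 x 2")
})

test_that("test choice follows the expected-count-below-5 rule", {
  expect_identical(choose_test(rbind(c(81, 5762), c(494, 9573))), "chi2")
  expect_identical(choose_test(rbind(c(3, 10), c(0, 10000))), "fisher")
  expect_identical(choose_test(rbind(c(5, 5), c(5, 5))), "chi2")  # boundary
})

test_that("chi-square and fisher agree on well-populated 2x2 tables", {
  set.seed(3)
  for (i in 1:25) {
    tab <- matrix(sample(50:400, 4, replace = TRUE), 2, 2)
    if (choose_test(tab) != "chi2") next
    expect_lt(abs(pearson_chi2_test(tab)$p_value - fisher_exact_2x2(tab)),
              0.02)
  }
})

test_that("crosstab reproduces the severity table with column percentages", {
  fx <- srs_fixture()
  ct <- crosstab(fx, "severity", "drug_class")
  expect_equal(ct$counts["serious", "mab"], 174L, ignore_attr = TRUE)
  expect_equal(ct$percents["serious", "mab"], 30.26)
  expect_equal(ct$counts["non_serious", "non_mab"], 10050L, ignore_attr = TRUE)
  expect_equal(ct$percents["non_serious", "non_mab"], 65.54)
  expect_identical(ct$test$method, "chi2")
  # column percentages sum to 100 within rounding slack
  expect_true(all(abs(colSums(ct$percents) - 100) <= 0.05))
})

test_that("degenerate crosstabs carry test NE", {
  one_col <- make_reports(6, severity = rep(c("serious", "non_serious"), 3))
  ct <- crosstab(one_col, "severity", "drug_class")
  expect_identical(ct$test$method, "NE")
  expect_true(all(!is.na(ct$percents)))
})

test_that("onset distribution drops missing onsets and reports the count", {
  rp <- make_reports(6, onset_days = c(0L, 2L, 2L, 5L, NA, NA))
  od <- onset_distribution(rp)
  expect_equal(od$n_missing, 2L)
  expect_equal(sum(od$table$n), 4L)
  expect_equal(od$table$pct[od$table$onset_bin == "d1_3"][1], 50)

  empty <- onset_distribution(make_reports(0))
  expect_equal(empty$n_missing, 0L)
  expect_equal(nrow(empty$table), 0L)
})

test_that("soc_table orders by total count and tests rows two-by-two", {
  mab_cols <- list(drug_class = "mab", drug_name = "Rituximab",
                   mab_type = "chimeric", patent_status = "branded")
  rp <- dplyr::bind_rows(
    make_reports(40, soc = "Gastrointestinal disorders"),
    do.call(make_reports, c(list(10, soc = "Gastrointestinal disorders"), mab_cols)),
    do.call(make_reports, c(list(2, soc = "Vascular disorders"), mab_cols)),
    make_reports(3, soc = "Vascular disorders"),
    make_reports(10, soc = "Eye disorders")
  )
  st <- soc_table(rp, "drug_class")
  expect_identical(st$soc[1], "Gastrointestinal disorders")
  expect_identical(st$test[st$soc == "Eye disorders"], "NE")     # zero mab cell
  expect_identical(st$test[st$soc == "Vascular disorders"], "fisher")
})
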