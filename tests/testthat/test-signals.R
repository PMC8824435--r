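# DEC contingency tables, disproportionality statistics and the signal
# criteria.

test_that("DEC tables partition the report set", {
  rp <- make_reports(4,
    drug_name = c("X", "X", "Y", "Y"),
    adr_term = c("e1", "e2", "e1", "e2")
  )
  dec <- build_dec_tables(rp)
  expect_equal(nrow(dec), 4L)
  xe1 <- dec[dec$drug_name == "X" & dec$adr_term == "e1", ]
  expect_equal(unlist(xe1[, c("a", "b", "c", "d")]), c(a = 1, b = 1, c = 1, d = 1),
               ignore_attr = TRUE)
  expect_true(all(dec$a + dec$b + dec$c + dec$d == 4))

  # a never-co-occurring pair is not emitted
  rp2 <- make_reports(3, drug_name = c("X", "X", "Y"),
                      adr_term = c("e1", "e1", "e2"))
  dec2 <- build_dec_tables(rp2)
  expect_equal(nrow(dec2), 2L)
  expect_false(any(dec2$drug_name == "X" & dec2$adr_term == "e2"))
})

test_that("DEC margins agree with independent drug and event tallies", {
  cfg <- sim_config(n_reports = 3000, seed = 17)
  db <- generate_reports(cfg)
  dec <- build_dec_tables(db)
  expect_true(all(dec$a + dec$b + dec$c + dec$d == nrow(db)))
  drug_tot <- table(db$drug_name)
  event_tot <- table(db$adr_term)
  expect_equal(dec$a + dec$b, as.integer(drug_tot[dec$drug_name]),
               ignore_attr = TRUE)
  expect_equal(dec$a + dec$c, as.integer(event_tot[dec$adr_term]),
               ignore_attr = TRUE)
})

test_that("ROR, PRR and MHRA chi-square match direct formula arithmetic", {
  got <- ror(10, 20, 30, 40)
  expect_equal(got$ror, 2 / 3, tolerance = 1e-12)
  expect_equal(c(got$ci_low, got$ci_high), woolf_ci_oracle(10, 20, 30, 40),
               tolerance = 1e-9)
  expect_equal(prr(20, 80, 30, 270)$prr, 2, tolerance = 1e-12)
  expect_equal(mhra_chi2(20, 80, 30, 270), 5.973333, tolerance = 1e-6)
  for (k in c(3, 7)) {
    expect_equal(ror(k, k, k, k)$ror, 1)
    expect_equal(prr(k, k, k, k)$prr, 1)
    expect_equal(mhra_chi2(k, k, k, k), 0)  # clamp active at |ad-bc| = 0
  }
})

test_that("doubling all cells keeps ROR fixed and narrows its CI", {
  r1 <- ror(10, 20, 30, 40)
  r2 <- ror(20, 40, 60, 80)
  expect_equal(r1$ror, r2$ror)
  expect_lt(r1$ci_low, r2$ci_low)
  expect_gt(r1$ci_high, r2$ci_high)
})

test_that("PRR increases monotonically in a with other cells fixed", {
  vals <- vapply(c(5, 10, 50, 200), function(a) prr(a, 10, 10, 100)$prr,
                 numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("undefined metrics are NA and never pass the criteria", {
  expect_true(is.na(ror(5, 0, 3, 10)$ror))
  expect_true(is.na(prr(5, 3, 0, 10)$prr))
  expect_true(is.na(mhra_chi2(0, 0, 3, 10)))
  dec <- tibble::tibble(drug_name = "X", adr_term = "e",
                        a = 50L, b = 0L, c = 3L, d = 100L)
  m <- evaluate_signal(dec)
  expect_false(m$signal)
})

test_that("Yates-corrected value never exceeds the uncorrected Pearson X2", {
  cells <- random_cells(200, seed = 13)
  for (i in seq_len(nrow(cells))) {
    tab <- matrix(unlist(cells[i, ]), 2, 2, byrow = TRUE)
    expect_lte(mhra_chi2(cells$a[i], cells$b[i], cells$c[i], cells$d[i]),
               chi2_oracle(tab) + 1e-12)
  }
})

test_that("ROR is at least PRR whenever PRR is at least 1", {
  cells <- random_cells(300, seed = 19)
  r <- ror(cells$a, cells$b, cells$c, cells$d)$ror
  p <- prr(cells$a, cells$b, cells$c, cells$d)$prr
  sel <- p >= 1
  expect_true(all(r[sel] >= p[sel] - 1e-12))
})

test_that("signal criteria require a >= 3 and all three methods by default", {
  # a = 2 with a huge disproportionality is never a signal
  small <- tibble::tibble(drug_name = "X", adr_term = "e",
                          a = 2L, b = 1L, c = 1L, d = 5000L)
  expect_false(evaluate_signal(small)$signal)

  # a strongly disproportionate DEC passes all three criteria
  strong <- tibble::tibble(drug_name = "PD1i", adr_term = "Pneumonitis",
                           a = 8L, b = 12L, c = 50L, d = 15840L)
  m <- evaluate_signal(strong)
  expect_true(m$ror_pass && m$prr_pass && m$mhra_pass && m$signal)

  # balanced tables never flag
  flat <- tibble::tibble(drug_name = "X", adr_term = "e",
                         a = 5L, b = 5L, c = 5L, d = 5L)
  mflat <- evaluate_signal(flat)
  expect_false(any(mflat$ror_pass, mflat$prr_pass, mflat$mhra_pass, mflat$signal))

  # union rule flags any single passing method
  ror_only <- tibble::tibble(drug_name = "X", adr_term = "e",
                             a = 40L, b = 1000L, c = 30L, d = 1400L)
  mi <- evaluate_signal(ror_only, rule = "intersection")
  mu <- evaluate_signal(ror_only, rule = "union")
  expect_true(mu$signal >= mi$signal)
})

test_that("the textbook PRR standard error is available and differs", {
  printed <- prr(20, 80, 30, 270, prr_se = "printed")
  textbook <- prr(20, 80, 30, 270, prr_se = "textbook")
  expect_equal(printed$prr, textbook$prr)
  expect_false(isTRUE(all.equal(printed$ci_low, textbook$ci_low)))
})

test_that("rank_signals orders by chi-square, is input-order invariant, and coherent", {
  cfg <- sim_config(n_reports = 20000, seed = 23,
                    planted_decs = tibble::tibble(
                      drug_name = c("Gefitinib", "Cisplatin"),
                      adr_term = c("Haemangioma", "Tinnitus"),
                      rate_ratio = c(12, 8)))
  db <- generate_reports(cfg)
  dec <- build_dec_tables(db)
  m <- evaluate_signal(dec)
  ranked <- rank_signals(m)
  expect_true(all(diff(ranked$chi2_yates) <= 0))
  shuffled <- rank_signals(evaluate_signal(dec[sample(nrow(dec)), ]))
  expect_equal(as.data.frame(ranked), as.data.frame(shuffled))
  # every emitted row re-satisfies the three criteria from its own cells
  for (i in seq_len(nrow(ranked))) {
    row <- m[m$drug_name == ranked$drug_name[i] & m$adr_term == ranked$adr_term[i], ]
    expect_gte(row$a, 3)
    expect_gt(ror(row$a, row$b, row$c, row$d)$ci_low, 1)
    p <- prr(row$a, row$b, row$c, row$d)
    expect_gte(p$prr, 2)
    expect_gt(p$ci_low, 1)
    expect_gte(mhra_chi2(row$a, row$b, row$c, row$d), 4)
  }
  # no passing DEC at all yields an empty table
  none <- tibble::tibble(drug_name = "X", adr_term = "e",
                         a = 5L, b = 5L, c = 5L, d = 5L)
  expect_equal(nrow(rank_signals(evaluate_signal(none))), 0L)
})
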