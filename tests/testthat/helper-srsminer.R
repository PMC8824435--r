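# Shared fixtures and independent oracles for the test suite.

# minimal valid report table; any field can be overridden per-column
make_reports <- function(n = 4, ...) {
  out <- tibble::tibble(
    report_id = sprintf("T%04d", seq_len(n)),
    year = rep(2019L, n),
    age = rep(55L, n),
    sex = rep(c("female", "male"), length.out = n),
    causality = rep("probable", n),
    drug_name = rep("Cisplatin", n),
    atc_class = rep("L01", n),
    drug_class = rep("non_mab", n),
    mab_type = rep("none", n),
    patent_status = rep("none", n),
    adr_term = rep("Nausea", n),
    soc = rep("Gastrointestinal disorders", n),
    onset_days = rep(1L, n),
    severity = rep("non_serious", n),
    impact = rep("no_effect", n),
    n_diseases = rep(1L, n),
    n_medications = rep(2L, n),
    past_adr_history = rep(FALSE, n),
    outcome_death = rep(FALSE, n)
  )
  dots <- list(...)
  for (nm in names(dots)) out[[nm]] <- dots[[nm]]
  out
}

# random strictly-positive 2x2 cell quadruples (as doubles: the oracles
# multiply four margins, which exceeds integer range)
random_cells <- function(n_tables, max_cell = 60, seed = 42) {
  set.seed(seed)
  tibble::tibble(
    a = as.numeric(sample.int(max_cell, n_tables, replace = TRUE)),
    b = as.numeric(sample.int(max_cell, n_tables, replace = TRUE)),
    c = as.numeric(sample.int(max_cell, n_tables, replace = TRUE)),
    d = as.numeric(sample.int(max_cell, n_tables, replace = TRUE))
  )
}

# brute-force Pearson X^2 = sum (O-E)^2/E, independent of stats::chisq.test
chi2_oracle <- function(tab) {
  tab <- as.matrix(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# full hypergeometric enumeration of the two-sided Fisher p-value
fisher_oracle <- function(tab) {
  tab <- as.matrix(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  avals <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  probs <- stats::dhyper(avals, cs[1], cs[2], rs[1])
  p_obs <- stats::dhyper(tab[1, 1], cs[1], cs[2], rs[1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# direct arithmetic of the three disproportionality formulas
ror_oracle <- function(a, b, c, d) (a * d) / (b * c)
prr_oracle <- function(a, b, c, d) (a / (a + b)) / (c / (c + d))
yates_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  num <- max(0, abs(a * d - b * c) - n / 2)^2 * n
  num / ((a + b) * (c + d) * (a + c) * (b + d))
}
woolf_ci_oracle <- function(a, b, c, d, z = stats::qnorm(0.975)) {
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(or * exp(-z * se), or * exp(z * se))
}
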