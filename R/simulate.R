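# Seeded synthetic-SRS generator: categorical marginals per field, per-class
# onset models, logistic outcome models, and planted drug-event signals with
# a specified reporting-rate ratio. Defaults emulate the marginal structure
# of the reference dataset (srs_fixture()).

AGE_GROUP_RANGES <- list("0-5" = 0:5, "6-17" = 6:17, "18-34" = 18:34,
                         "35-59" = 35:59, "60-79" = 60:79, ">=80" = 80:95)
ONSET_BIN_RANGES <- list(same_day = 0L, d1_3 = 1:3, d4_7 = 4:7,
                         d8_30 = 8:30, d_gt30 = 31:90)
IMPACT_EFFECT_SPLIT <- c(prolong = 133, worse = 2499, sequelae = 14, death = 4)

default_drug_catalog <- function() {
  mab <- FIXTURE_MAB_DRUGS
  mab$drug_class <- "mab"
  mab$patent_status <- "branded"
  # biosimilar share (80/575) carried by the three originators that have
  # marketed follow-on products
  bios <- data.frame(
    drug_name = c("Rituximab", "Trastuzumab", "Bevacizumab"),
    mab_type = c("chimeric", "humanized", "humanized"),
    n = c(30, 30, 20), drug_class = "mab", patent_status = "biosimilar",
    stringsAsFactors = FALSE
  )
  mab$n[match(bios$drug_name, mab$drug_name)] <-
    mab$n[match(bios$drug_name, mab$drug_name)] - bios$n
  non <- data.frame(
    drug_name = FIXTURE_NONMAB_DRUGS, mab_type = "none",
    n = NA_real_, drug_class = "non_mab", patent_status = "none",
    stringsAsFactors = FALSE
  )
  non$n <- 15335 / nrow(non)
  out <- rbind(mab, bios, non)
  tibble::tibble(drug_name = out$drug_name, drug_class = out$drug_class,
                 mab_type = out$mab_type, patent_status = out$patent_status,
                 weight = out$n / sum(out$n))
}

default_event_catalog <- function() {
  terms <- soc_term_map()
  mab_soc <- stats::setNames(
    FIXTURE_MAB_SOC_PATENT$branded + FIXTURE_MAB_SOC_PATENT$biosimilar,
    FIXTURE_MAB_SOC_PATENT$soc
  )
  soc_tot <- stats::setNames(FIXTURE_NONMAB_SOC, FIXTURE_SOCS)
  soc_tot[names(mab_soc)] <- soc_tot[names(mab_soc)] + mab_soc
  # split each SOC's share equally over its terms
  n_terms <- table(terms$soc)
  p <- as.numeric(soc_tot[terms$soc]) / as.numeric(n_terms[terms$soc])
  tibble::tibble(adr_term = terms$adr_term, soc = terms$soc,
                 baseline = p / sum(p))
}

#' Simulation configuration for a synthetic SRS database
#'
#' Assembles (and validates) the generative model for [generate_reports()]:
#' categorical marginals per field, a drug catalogue with sampling weights,
#' an event catalogue with baseline reporting probabilities, planted
#' drug-event combinations with a reporting-rate ratio, per-drug-class
#' onset-bin distributions, and logistic outcome models for severity and
#' impact. Every default emulates the marginal structure of the reference
#' dataset; pass replacements to override individual components.
#'
#' @param n_reports Number of reports to generate.
#' @param seed Integer seed; identical config + seed reproduces the
#'   identical table.
#' @param marginals Named list of probability vectors: `year`, `sex`,
#'   `age_group`, `causality`, `n_diseases`, `n_medications`, plus scalars
#'   `p_history`, `p_age_missing`, `p_onset_missing`.
#' @param drug_catalog Tibble: `drug_name`, `drug_class`, `mab_type`,
#'   `patent_status`, `weight` (weights sum to 1).
#' @param event_catalog Tibble: `adr_term`, `soc`, `baseline` (baselines
#'   sum to 1).
#' @param planted_decs Tibble with `drug_name`, `adr_term`,
#'   `rate_ratio` (> 0): within reports of that drug, the event's baseline
#'   probability is multiplied by `rate_ratio` and the event distribution
#'   renormalised.
#' @param onset_model Named list (`mab`, `non_mab`) of probability vectors
#'   over the onset bins; days are drawn uniformly within the bin.
#' @param outcome_model List with elements `severity` and `impact`, each a
#'   named coefficient vector `c(intercept, mab, female, multiple, poly,
#'   history)` on the logit scale.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_reports = 15910, seed = 1L, marginals = list(),
                       drug_catalog = NULL, event_catalog = NULL,
                       planted_decs = NULL, onset_model = NULL,
                       outcome_model = NULL) {
  defaults <- list(
    year = c("2016" = 1404, "2017" = 1853, "2018" = 2488,
             "2019" = 4005, "2020" = 6160) / 15910,
    sex = c(male = 7206, female = 8691, unknown = 13) / 15910,
    age_group = stats::setNames(c(196, 235, 448, 6950, 7706, 331) / 15866,
                                AGE_GROUPS),
    causality = c(certain = 0.1, probable = 0.6, possible = 0.3),
    n_diseases = c("1" = 0.8829, "2" = 0.0935, "3" = 0.0180, "4" = 0.0056),
    n_medications = c("1" = 0.40, "2" = 0.30, "3" = 0.15, "4" = 0.0886,
                      "5" = 0.03, "6" = 0.02, "7" = 0.008, "8" = 0.0034),
    p_history = 1082 / 15910,
    p_age_missing = 44 / 15910,
    p_onset_missing = 6 / 15910
  )
  marg <- utils::modifyList(defaults, marginals)
  cfg <- list(
    n_reports = as.integer(n_reports),
    seed = as.integer(seed),
    marginals = marg,
    drug_catalog = if (is.null(drug_catalog)) default_drug_catalog() else drug_catalog,
    event_catalog = if (is.null(event_catalog)) default_event_catalog() else event_catalog,
    planted_decs = if (is.null(planted_decs)) {
      tibble::tibble(drug_name = character(), adr_term = character(),
                     rate_ratio = numeric())
    } else tibble::as_tibble(planted_decs),
    onset_model = if (is.null(onset_model)) {
      list(mab = stats::setNames(c(297, 150, 60, 50, 18) / 575, ONSET_BINS),
           non_mab = stats::setNames(c(4000, 4929, 4127, 1500, 773) / 15329,
                                     ONSET_BINS))
    } else onset_model,
    outcome_model = if (is.null(outcome_model)) {
      list(severity = c(intercept = qlogis(0.40), mab = -0.213, female = -0.237,
                        multiple = 0.175, poly = -0.859, history = 0.587),
            impact = c(intercept = qlogis(0.19), mab = -0.418, female = -0.158,
                       multiple = 0.239, poly = -1.166, history = 0.587))
    } else outcome_model
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  problems <- character()
  chk_prob <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      problems <<- c(problems, paste0("`", what, "` is not a probability vector ",
                                      "(non-negative, summing to 1 within 1e-9)"))
    }
  }
  for (nm in c("year", "sex", "age_group", "causality", "n_diseases",
               "n_medications")) {
    chk_prob(cfg$marginals[[nm]], nm)
  }
  chk_prob(cfg$drug_catalog$weight, "drug_catalog$weight")
  chk_prob(cfg$event_catalog$baseline, "event_catalog$baseline")
  for (nm in names(cfg$onset_model)) {
    chk_prob(cfg$onset_model[[nm]], paste0("onset_model$", nm))
  }
  if (nrow(cfg$planted_decs) > 0) {
    if (any(cfg$planted_decs$rate_ratio <= 0)) {
      problems <- c(problems, "planted rate_ratio must be > 0")
    }
    if (!all(cfg$planted_decs$drug_name %in% cfg$drug_catalog$drug_name)) {
      problems <- c(problems, "planted drug not in drug_catalog")
    }
    if (!all(cfg$planted_decs$adr_term %in% cfg$event_catalog$adr_term)) {
      problems <- c(problems, "planted ADR term not in event_catalog")
    }
  }
  if (cfg$n_reports < 1) problems <- c(problems, "n_reports must be >= 1")
  if (length(problems) > 0) {
    stop("invalid simulation config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' Accepts the [sim_config()] arguments as top-level keys; probability
#' vectors are named maps, catalogues and planted DECs lists of records.
#' Omitted keys fall back to the defaults.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's `seed`.
#' @return A validated `sim_config`.
#' @export
sim_config_from_yaml <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  as_tbl <- function(x) if (is.null(x)) NULL else dplyr::bind_rows(lapply(x, tibble::as_tibble))
  as_num <- function(x) if (is.null(x)) NULL else unlist(x)
  sim_config(
    n_reports = if (is.null(y$n_reports)) 15910 else y$n_reports,
    seed = if (!is.null(seed)) seed else if (is.null(y$seed)) 1L else y$seed,
    marginals = if (is.null(y$marginals)) list() else lapply(y$marginals, function(v) {
      if (length(v) > 1) unlist(v) else v
    }),
    drug_catalog = as_tbl(y$drug_catalog),
    event_catalog = as_tbl(y$event_catalog),
    planted_decs = as_tbl(y$planted_decs),
    onset_model = if (is.null(y$onset_model)) NULL else lapply(y$onset_model, as_num),
    outcome_model = if (is.null(y$outcome_model)) NULL else lapply(y$outcome_model, as_num)
  )
}

# event distribution per drug: baseline, or baseline reweighted by the
# planted rate ratios for that drug, renormalised
event_probs_for_drug <- function(cfg, drug) {
  p <- cfg$event_catalog$baseline
  hits <- cfg$planted_decs[cfg$planted_decs$drug_name == drug, ]
  if (nrow(hits) > 0) {
    idx <- match(hits$adr_term, cfg$event_catalog$adr_term)
    p[idx] <- p[idx] * hits$rate_ratio
    p <- p / sum(p)
  }
  p
}

#' Generate a synthetic SRS database
#'
#' Draws `n_reports` reports from the generative model in `config`. Fields
#' are drawn independently per the marginals except that (i) the ADR term
#' is drawn from the event baselines reweighted by the planted rate ratio
#' for the report's drug, (ii) onset bins follow the per-drug-class onset
#' model with uniform days within the bin, and (iii) severity and the
#' dichotomised impact are Bernoulli with log-odds from the outcome models
#' (covariates: mAb, female, multiple diseases, polypharmacy, past ADR
#' history). The random stream is consumed in a fixed field order (year,
#' sex, age, drug, event, onset, diseases, medications, history, causality,
#' severity, impact), so identical config + seed reproduces the identical
#' table.
#'
#' @param config A `sim_config`.
#' @return Report tibble in the canonical schema.
#' @export
generate_reports <- function(config) {
  validate_sim_config(config)
  cfg <- config
  n <- cfg$n_reports
  m <- cfg$marginals
  set.seed(cfg$seed)

  draw_cat <- function(p) names(p)[sample.int(length(p), n, replace = TRUE, prob = p)]

  year <- as.integer(draw_cat(m$year))
  sex <- draw_cat(m$sex)
  grp <- draw_cat(m$age_group)
  age_missing <- runif(n) < m$p_age_missing
  age <- integer(n)
  for (g in names(AGE_GROUP_RANGES)) {
    rows <- which(grp == g)
    if (length(rows) == 0) next
    r <- AGE_GROUP_RANGES[[g]]
    age[rows] <- r[sample.int(length(r), length(rows), replace = TRUE)]
  }
  age[age_missing] <- NA_integer_

  drug_idx <- sample.int(nrow(cfg$drug_catalog), n, replace = TRUE,
                         prob = cfg$drug_catalog$weight)
  drug <- cfg$drug_catalog[drug_idx, ]

  ev_idx <- integer(n)
  for (dn in unique(drug$drug_name)) {
    rows <- which(drug$drug_name == dn)
    ev_idx[rows] <- sample.int(nrow(cfg$event_catalog), length(rows),
                               replace = TRUE,
                               prob = event_probs_for_drug(cfg, dn))
  }
  event <- cfg$event_catalog[ev_idx, ]

  onset <- integer(n)
  for (cl in c("mab", "non_mab")) {
    rows <- which(drug$drug_class == cl)
    if (length(rows) == 0) next
    pb <- cfg$onset_model[[cl]]
    bins <- names(pb)[sample.int(length(pb), length(rows), replace = TRUE, prob = pb)]
    for (bn in names(ONSET_BIN_RANGES)) {
      brows <- rows[bins == bn]
      if (length(brows) == 0) next
      r <- ONSET_BIN_RANGES[[bn]]
      onset[brows] <- if (length(r) == 1L) r else
        r[sample.int(length(r), length(brows), replace = TRUE)]
    }
  }
  onset[runif(n) < m$p_onset_missing] <- NA_integer_

  n_dis <- as.integer(draw_cat(m$n_diseases))
  n_med <- as.integer(draw_cat(m$n_medications))
  history <- runif(n) < m$p_history
  causality <- draw_cat(m$causality)

  x_mab <- as.numeric(drug$drug_class == "mab")
  x_fem <- as.numeric(sex == "female")
  x_mul <- as.numeric(n_dis > 1)
  x_pol <- as.numeric(n_med >= 5)
  x_his <- as.numeric(history)
  lp <- function(beta) {
    beta[["intercept"]] + beta[["mab"]] * x_mab + beta[["female"]] * x_fem +
      beta[["multiple"]] * x_mul + beta[["poly"]] * x_pol + beta[["history"]] * x_his
  }
  serious <- runif(n) < plogis(lp(cfg$outcome_model$severity))
  effect <- runif(n) < plogis(lp(cfg$outcome_model$impact))
  sub <- sample(names(IMPACT_EFFECT_SPLIT), n, replace = TRUE,
                prob = IMPACT_EFFECT_SPLIT / sum(IMPACT_EFFECT_SPLIT))
  impact <- ifelse(effect, sub, "no_effect")

  tibble::tibble(
    report_id = sprintf("S%07d", seq_len(n)),
    year = year, age = age, sex = sex, causality = causality,
    drug_name = drug$drug_name, atc_class = "L01",
    drug_class = drug$drug_class, mab_type = drug$mab_type,
    patent_status = drug$patent_status,
    adr_term = event$adr_term, soc = event$soc,
    onset_days = onset,
    severity = ifelse(serious, "serious", "non_serious"),
    impact = impact,
    n_diseases = n_dis, n_medications = n_med,
    past_adr_history = history,
    outcome_death = impact == "death"
  )
}

#' Analytic expected 2 x 2 cells for every drug-event combination
#'
#' Expectation of the DEC contingency cells under the generative model:
#' E[a] = n * P(drug) * P(event | drug), with the planted rate-ratio
#' reweighting included. This is the closed-form oracle against which the
#' empirical tables from [generate_reports()] + [build_dec_tables()] can be
#' checked.
#'
#' @param config A `sim_config`.
#' @return Tibble: `drug_name`, `adr_term`, `e_a`, `e_b`, `e_c`, `e_d`.
#' @export
expected_dec_counts <- function(config) {
  cfg <- config
  n <- cfg$n_reports
  w <- tapply(cfg$drug_catalog$weight, cfg$drug_catalog$drug_name, sum)
  drugs <- names(w)
  pmat <- vapply(drugs, function(dn) event_probs_for_drug(cfg, dn),
                 numeric(nrow(cfg$event_catalog)))
  # marginal event probability: sum_d w_d p(e|d)
  p_event <- as.numeric(pmat %*% as.numeric(w[drugs]))
  out <- lapply(seq_along(drugs), function(j) {
    e_a <- n * w[[j]] * pmat[, j]
    e_ab <- n * w[[j]]
    e_ac <- n * p_event
    tibble::tibble(drug_name = drugs[j],
                   adr_term = cfg$event_catalog$adr_term,
                   e_a = e_a, e_b = e_ab - e_a, e_c = e_ac - e_a,
                   e_d = n - e_ab - e_ac + e_a)
  })
  dplyr::bind_rows(out)
}

#' Operating characteristics of the signal criteria under replication
#'
#' Repeatedly generates databases from `config` (seeds derived
#' deterministically from `config$seed`), mines signals, and reports the
#' fraction of replicates in which each planted DEC is flagged, together
#' with the false-flag fraction over a seeded sample of non-planted DECs
#' whose expected report count `E[a]` is at least `min_expected_a`.
#'
#' @param config A `sim_config` (typically with `planted_decs`).
#' @param n_replicates Number of replicate databases (>= 1).
#' @param rule Signal combination rule, passed to [evaluate_signal()].
#' @param n_null_decs Number of non-planted DECs to monitor (default 20).
#' @param min_expected_a Minimum analytic `E[a]` for monitored null DECs.
#' @return Tibble: `drug_name`, `adr_term`, `planted`, `rate_ratio`,
#'   `expected_a`, `n_flagged`, `n_replicates`, `detection_rate`.
#' @export
operating_characteristics <- function(config, n_replicates,
                                      rule = c("intersection", "union"),
                                      n_null_decs = 20L, min_expected_a = 10) {
  rule <- match.arg(rule)
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  cfg <- config
  expected <- expected_dec_counts(cfg)
  planted_key <- paste(cfg$planted_decs$drug_name, cfg$planted_decs$adr_term)
  expected$planted <- paste(expected$drug_name, expected$adr_term) %in% planted_key

  null_pool <- expected[!expected$planted & expected$e_a >= min_expected_a, ]
  set.seed(derive_seed(cfg$seed, 0L))
  take <- min(n_null_decs, nrow(null_pool))
  null_pick <- null_pool[sample.int(nrow(null_pool), take), ]

  watch <- dplyr::bind_rows(
    expected[expected$planted, c("drug_name", "adr_term", "e_a")],
    null_pick[, c("drug_name", "adr_term", "e_a")]
  )
  watch$planted <- c(rep(TRUE, sum(expected$planted)), rep(FALSE, take))
  watch$rate_ratio <- 1
  if (nrow(cfg$planted_decs) > 0) {
    idx <- match(paste(watch$drug_name, watch$adr_term), planted_key)
    watch$rate_ratio[!is.na(idx)] <- cfg$planted_decs$rate_ratio[idx[!is.na(idx)]]
  }
  flags <- matrix(0L, nrow(watch), n_replicates)
  for (i in seq_len(n_replicates)) {
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(cfg$seed, i)
    db <- generate_reports(cfg_i)
    metrics <- evaluate_signal(build_dec_tables(db), rule = rule)
    hit <- paste(metrics$drug_name, metrics$adr_term)[metrics$signal]
    flags[, i] <- as.integer(paste(watch$drug_name, watch$adr_term) %in% hit)
  }
  tibble::tibble(
    drug_name = watch$drug_name, adr_term = watch$adr_term,
    planted = watch$planted, rate_ratio = watch$rate_ratio,
    expected_a = watch$e_a,
    n_flagged = rowSums(flags), n_replicates = n_replicates,
    detection_rate = rowSums(flags) / n_replicates
  )
}
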