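# Deterministic reference dataset: 15,910 retained-grade anticancer-drug ADR
# reports whose marginal counts reproduce, cell for cell, the published
# provincial-SRS comparison of mAb vs non-mAb reports (age group, sex, year,
# disease types, polypharmacy, past ADR history, SOC by drug class, severity
# and impact by drug class, SOC by patent status within mAbs, and the two
# published onset-bin counts). Joint structure beyond those constraints is
# arbitrary but fixed: each variable is laid out in contiguous blocks, so
# the same config always yields the identical table.

#' Bundled synthetic term-to-SOC map
#'
#' A small mock MedDRA-like dictionary mapping ADR preferred-term-like
#' labels to system organ class (SOC) labels. It is a synthetic stand-in
#' bundled with the package; it is not the licensed MedDRA dictionary.
#'
#' @return Tibble with columns `adr_term`, `soc`.
#' @export
soc_term_map <- function() {
  path <- system.file("extdata", "soc_terms_synthetic.csv", package = "srsminer")
  readr::read_csv(path, col_types = "cc", progress = FALSE)
}

# SOC labels in published-table order (largest overall first)
FIXTURE_SOCS <- c(
  "Gastrointestinal disorders",
  "Blood and lymphatic system disorders",
  "Skin and subcutaneous tissue disorders",
  "Investigations",
  "General disorders and administration site conditions",
  "Nervous system disorders",
  "Respiratory, thoracic, and mediastinal disorders",
  "Vascular disorders",
  "Musculoskeletal and connective tissue disorders",
  "Cardiac disorders",
  "Hepatobiliary disorders",
  "Metabolism and nutrition disorders",
  "Immune system disorders",
  "Renal and urinary disorders",
  "Endocrine disorders",
  "Psychiatric disorders",
  "Eye disorders",
  "Injury, poisoning, and procedural complications",
  "Neoplasms benign, malignant, and unspecified (including cysts and polyps)",
  "Ear and labyrinth disorders",
  "Infections and infestations",
  "Reproductive system and breast disorders"
)

# mAb SOC x patent-status cells (branded, biosimilar); row sums equal the
# mAb SOC margin and column sums are 495 branded / 80 biosimilar
FIXTURE_MAB_SOC_PATENT <- data.frame(
  soc = c(
    "General disorders and administration site conditions",
    "Skin and subcutaneous tissue disorders",
    "Gastrointestinal disorders",
    "Blood and lymphatic system disorders",
    "Respiratory, thoracic, and mediastinal disorders",
    "Cardiac disorders",
    "Vascular disorders",
    "Investigations",
    "Endocrine disorders",
    "Nervous system disorders",
    "Immune system disorders",
    "Hepatobiliary disorders",
    "Neoplasms benign, malignant, and unspecified (including cysts and polyps)",
    "Renal and urinary disorders",
    "Metabolism and nutrition disorders",
    "Musculoskeletal and connective tissue disorders",
    "Injury, poisoning, and procedural complications"
  ),
  branded    = c(122, 75, 74, 41, 38, 23, 19, 17, 18, 15, 12, 11, 11, 6, 5, 5, 3),
  biosimilar = c(20, 12, 7, 9, 12, 5, 3, 3, 1, 3, 2, 1, 0, 2, 0, 0, 0),
  stringsAsFactors = FALSE
)

# non-mAb SOC margin, published-table order
FIXTURE_NONMAB_SOC <- c(5762, 3559, 1263, 1158, 833, 616, 578, 264, 276, 249,
                        251, 204, 166, 72, 17, 20, 16, 10, 1, 10, 6, 4)

# mAb drug catalogue with published report counts, by antibody type
FIXTURE_MAB_DRUGS <- data.frame(
  drug_name = c("Rituximab", "Cetuximab",
                "Trastuzumab", "Bevacizumab", "Camrelizumab", "Toripalimab",
                "Pembrolizumab", "Pertuzumab", "Nimotuzumab", "Tislelizumab",
                "Atezolizumab", "Tocilizumab",
                "Sintilimab", "Evolocumab", "Nivolumab", "Adalimumab"),
  mab_type = c(rep("chimeric", 2), rep("humanized", 10), rep("fully_human", 4)),
  n = c(130, 38, 171, 77, 60, 15, 10, 9, 7, 2, 1, 1, 48, 3, 2, 1),
  stringsAsFactors = FALSE
)

FIXTURE_NONMAB_DRUGS <- c(
  "Cisplatin", "Carboplatin", "Oxaliplatin", "Paclitaxel", "Docetaxel",
  "Fluorouracil", "Gemcitabine", "Cyclophosphamide", "Etoposide",
  "Gefitinib", "Regorafenib", "Recombinant human interleukin-2"
)

# representative age per age group (deterministic; only the group matters
# for the published tables)
FIXTURE_GROUP_AGE <- c(3L, 12L, 26L, 47L, 70L, 85L)

# representative onset day per onset bin
FIXTURE_BIN_DAY <- c(same_day = 0L, d1_3 = 2L, d4_7 = 5L, d8_30 = 15L, d_gt30 = 45L)

#' Deterministic reference SRS dataset
#'
#' Builds the bundled reference database of 15,910 anticancer-drug ADR
#' reports (575 mAb, 15,335 non-mAb) whose marginal counts reproduce a
#' published provincial spontaneous-reporting-system safety comparison:
#' age-group, sex, year, disease-type, polypharmacy and past-ADR-history
#' margins per drug class; SOC margins per drug class and, within mAbs,
#' jointly with patent status (branded vs biosimilar); severity and impact
#' margins per drug class; and the two published onset-bin counts (297 mAb
#' same-day reports; 4,929 non-mAb reports at 1-3 days) among the 15,904
#' reports with known onset. 44 non-mAb reports carry missing age and 13
#' missing sex, matching the published per-analysis exclusions; 6 non-mAb
#' reports carry missing onset.
#'
#' Joint structure beyond these constraints is arbitrary but fixed: the
#' function is fully deterministic (no random number use) and always returns
#' the identical table.
#'
#' @return Report tibble in the canonical schema (see [parse_reports()]).
#' @examples
#' fx <- srs_fixture()
#' table(fx$drug_class)  # 575 mab, 15335 non_mab
#' @export
srs_fixture <- function() {
  terms <- soc_term_map()
  term_cycle <- function(socs) {
    # SOC values arrive in contiguous blocks; cycle each SOC's terms within
    # its block, deterministically
    f <- factor(socs, levels = unique(socs))
    unlist(lapply(split(seq_along(socs), f), function(idx) {
      pool <- terms$adr_term[terms$soc == socs[idx[1]]]
      rep_len(pool, length(idx))
    }), use.names = FALSE)
  }

  ## --- mAb block (575 reports) -------------------------------------------
  n_mab <- 575L
  mab_soc    <- rep(FIXTURE_MAB_SOC_PATENT$soc,
                    FIXTURE_MAB_SOC_PATENT$branded + FIXTURE_MAB_SOC_PATENT$biosimilar)
  mab_patent <- unlist(mapply(function(b, s) c(rep("branded", b), rep("biosimilar", s)),
                              FIXTURE_MAB_SOC_PATENT$branded,
                              FIXTURE_MAB_SOC_PATENT$biosimilar, SIMPLIFY = FALSE),
                       use.names = FALSE)
  mab <- tibble::tibble(
    year  = rep(2016:2020, c(6L, 19L, 33L, 140L, 377L)),
    age   = rep(FIXTURE_GROUP_AGE, c(3L, 4L, 26L, 265L, 254L, 23L)),
    sex   = rep(c("female", "male"), c(328L, 247L)),
    drug_name = rep(FIXTURE_MAB_DRUGS$drug_name, FIXTURE_MAB_DRUGS$n),
    mab_type  = rep(FIXTURE_MAB_DRUGS$mab_type, FIXTURE_MAB_DRUGS$n),
    drug_class = "mab",
    patent_status = mab_patent,
    soc = mab_soc,
    adr_term = term_cycle(mab_soc),
    onset_days = rep(unname(FIXTURE_BIN_DAY), c(297L, 150L, 60L, 50L, 18L)),
    severity = rep(c("serious", "non_serious"), c(174L, 401L)),
    impact = rep(c("sequelae", "worse", "prolong", "no_effect"),
                 c(1L, 58L, 10L, 506L)),
    n_diseases = rep(c(1L, 2L), c(508L, 67L)),
    n_medications = rep(c(5L, 2L), c(37L, 538L)),
    past_adr_history = rep(c(TRUE, FALSE), c(26L, 549L))
  )

  ## --- non-mAb block (15,335 reports) ------------------------------------
  n_non <- 15335L
  non_soc <- rep(FIXTURE_SOCS, FIXTURE_NONMAB_SOC)
  non <- tibble::tibble(
    year = rep(2016:2020, c(1398L, 1834L, 2455L, 3865L, 5783L)),
    age  = c(rep(FIXTURE_GROUP_AGE, c(193L, 231L, 422L, 6685L, 7452L, 308L)),
             rep(NA_integer_, 44L)),
    sex  = rep(c("female", "male", "unknown"), c(8363L, 6959L, 13L)),
    drug_name = rep_len(FIXTURE_NONMAB_DRUGS, n_non),
    mab_type = "none",
    drug_class = "non_mab",
    patent_status = "none",
    soc = non_soc,
    adr_term = term_cycle(non_soc),
    onset_days = c(rep(unname(FIXTURE_BIN_DAY), c(4000L, 4929L, 4127L, 1500L, 773L)),
                   rep(NA_integer_, 6L)),
    # deaths first so that outcome_death rows fall inside the serious block
    severity = rep(c("serious", "non_serious"), c(5285L, 10050L)),
    impact = rep(c("death", "sequelae", "worse", "prolong", "no_effect"),
                 c(4L, 13L, 2441L, 123L, 12754L)),
    n_diseases = rep(c(1L, 2L), c(13539L, 1796L)),
    n_medications = rep(c(5L, 2L), c(940L, 14395L)),
    past_adr_history = rep(c(TRUE, FALSE), c(1056L, 14279L))
  )

  out <- dplyr::bind_rows(mab, non)
  out$report_id <- sprintf("R%05d", seq_len(n_mab + n_non))
  out$causality <- "probable"
  out$atc_class <- "L01"
  out$outcome_death <- out$impact == "death"
  out[ADR_COLUMNS]
}
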