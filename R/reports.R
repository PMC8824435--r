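# Report data model: one row per spontaneous ADR report, CSV ingest/output,
# inclusion/exclusion filtering and the standard variable codings.

# canonical column set; every report table carries exactly these columns
ADR_COLUMNS <- c(
  "report_id", "year", "age", "sex", "causality", "drug_name", "atc_class",
  "drug_class", "mab_type", "patent_status", "adr_term", "soc", "onset_days",
  "severity", "impact", "n_diseases", "n_medications", "past_adr_history",
  "outcome_death"
)

SEX_LEVELS       <- c("male", "female", "unknown")
CAUSALITY_LEVELS <- c("certain", "probable", "possible", "other")
DRUG_CLASSES     <- c("mab", "non_mab")
MAB_TYPES        <- c("chimeric", "humanized", "fully_human", "none")
PATENT_LEVELS    <- c("branded", "biosimilar", "none")
SEVERITY_LEVELS  <- c("serious", "non_serious")
IMPACT_LEVELS    <- c("no_effect", "prolong", "worse", "sequelae", "death")
ONSET_BINS       <- c("same_day", "d1_3", "d4_7", "d8_30", "d_gt30")
AGE_GROUPS       <- c("0-5", "6-17", "18-34", "35-59", "60-79", ">=80")

INTEGER_COLUMNS <- c("year", "age", "onset_days", "n_diseases", "n_medications")
LOGICAL_COLUMNS <- c("past_adr_history", "outcome_death")

#' Read spontaneous ADR reports from CSV
#'
#' Parses a long-format report table (one row per report) into the canonical
#' schema. Parsing is deliberately separate from filtering: rows with missing
#' age or other excludable content are kept here and removed later by
#' [apply_inclusion_filters()].
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param dialect Optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(adr_term = "PT_NAME")`, so
#'   arbitrary export dialects can be adapted.
#' @return A tibble with the canonical columns (see [srs_fixture()] for the
#'   schema). Rows whose `report_id` or `year` cannot be parsed are skipped
#'   and recorded in the `"skipped_rows"` attribute. Unknown enum labels are
#'   mapped to `"unknown"`/`"other"` with a warning; missing numeric cells
#'   become `NA`, never sentinel numbers.
#' @export
parse_reports <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("input file does not exist: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      if (!dialect[[canon]] %in% names(raw)) {
        stop("dialect maps `", canon, "` to missing column `", dialect[[canon]], "`",
             call. = FALSE)
      }
      names(raw)[names(raw) == dialect[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(ADR_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("required column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[ADR_COLUMNS]

  for (col in INTEGER_COLUMNS) {
    val <- suppressWarnings(as.integer(raw[[col]]))
    raw[[col]] <- val
  }
  for (col in LOGICAL_COLUMNS) {
    raw[[col]] <- parse_flag(raw[[col]])
  }

  # rows without an id or a parseable year cannot be tracked through the
  # filter log; record and drop them
  bad <- is.na(raw$report_id) | raw$report_id == "" | is.na(raw$year)
  skipped <- raw$report_id[bad]
  if (any(bad)) {
    warning(sum(bad), " unparseable row(s) skipped", call. = FALSE)
    raw <- raw[!bad, ]
  }

  raw$sex       <- coerce_enum(raw$sex, SEX_LEVELS, "unknown", "sex")
  raw$causality <- coerce_enum(raw$causality, CAUSALITY_LEVELS, "other", "causality")
  raw$drug_class    <- coerce_enum(raw$drug_class, DRUG_CLASSES, NA_character_, "drug_class")
  raw$mab_type      <- coerce_enum(raw$mab_type, MAB_TYPES, "none", "mab_type")
  raw$patent_status <- coerce_enum(raw$patent_status, PATENT_LEVELS, "none", "patent_status")
  raw$severity  <- coerce_enum(raw$severity, SEVERITY_LEVELS, NA_character_, "severity")
  raw$impact    <- coerce_enum(raw$impact, IMPACT_LEVELS, NA_character_, "impact")

  out <- tibble::as_tibble(raw)
  attr(out, "skipped_rows") <- skipped
  out
}

parse_flag <- function(x) {
  lx <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[lx %in% c("false", "f", "no", "n", "0")] <- FALSE
  out
}

coerce_enum <- function(x, levels, fallback, field) {
  lx <- tolower(trimws(x))
  bad <- !is.na(lx) & lx != "" & !(lx %in% levels)
  if (any(bad)) {
    warning(sum(bad), " unrecognised `", field, "` label(s) mapped to `",
            fallback, "`", call. = FALSE)
    lx[bad] <- fallback
  }
  lx[!is.na(lx) & lx == ""] <- NA_character_
  lx
}

#' Write ADR reports to CSV
#'
#' Inverse of [parse_reports()]: writing retained reports and re-parsing
#' yields field-identical records.
#'
#' @param reports Report tibble in the canonical schema.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path) {
  readr::write_csv(reports[ADR_COLUMNS], path, progress = FALSE)
  invisible(path)
}

# ordered exclusion rules; each excluded report is attributed to the FIRST
# rule it violates, so filter accounting is exact
FILTER_RULES <- c("year", "causality", "atc", "missing-info", "age>120",
                  "negative-onset", "duplicate")

#' Apply the report inclusion/exclusion criteria
#'
#' Retains reports with: calendar year 2016-2020; causality assessed as
#' certain, probable or possible; suspect drug in ATC class L01
#' (antineoplastic agents); known age not above 120 years; non-missing drug
#' name and ADR term; non-negative onset time when recorded; and no earlier
#' retained duplicate (duplicate key: year, age, sex, drug name, ADR term,
#' onset days). Filtering never throws on content; every excluded report is
#' logged with its first matching rule.
#'
#' @param reports Report tibble in the canonical schema.
#' @return A list with elements `retained` (tibble) and `log` (a
#'   `filter_report`: `n_input`, `n_retained`, per-rule `exclusions`, and a
#'   per-report `exclusion_log` with columns `report_id`, `rule_id`).
#' @export
apply_inclusion_filters <- function(reports) {
  n <- nrow(reports)
  rule <- rep(NA_character_, n)

  fails <- list(
    "year"           = is.na(reports$year) | reports$year < 2016 | reports$year > 2020,
    "causality"      = !(reports$causality %in% c("certain", "probable", "possible")),
    "atc"            = is.na(reports$atc_class) | reports$atc_class != "L01",
    "missing-info"   = is.na(reports$age) | is.na(reports$drug_name) |
                       reports$drug_name == "" | is.na(reports$adr_term) |
                       reports$adr_term == "",
    "age>120"        = !is.na(reports$age) & reports$age > 120,
    "negative-onset" = !is.na(reports$onset_days) & reports$onset_days < 0
  )
  for (r in names(fails)) {
    hit <- fails[[r]] & is.na(rule)
    rule[hit] <- r
  }

  # duplicates are judged among reports surviving every earlier rule, in
  # file order: the first occurrence is kept
  surv <- is.na(rule)
  key <- paste(reports$year, reports$age, reports$sex, reports$drug_name,
               reports$adr_term, reports$onset_days, sep = "\r")
  dup <- surv & duplicated(ifelse(surv, key, paste0("\x01", seq_len(n))))
  rule[dup] <- "duplicate"

  retained <- reports[is.na(rule), ]
  excl <- tibble::tibble(report_id = reports$report_id[!is.na(rule)],
                         rule_id = rule[!is.na(rule)])
  counts <- tibble::tibble(
    rule_id = FILTER_RULES,
    n = vapply(FILTER_RULES, function(r) sum(excl$rule_id == r), integer(1))
  )
  log <- structure(
    list(n_input = n, n_retained = nrow(retained),
         exclusions = counts, exclusion_log = excl),
    class = "filter_report"
  )
  list(retained = retained, log = log)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Report filter log\n")
  cat("  input:    ", x$n_input, "\n")
  cat("  retained: ", x$n_retained, "\n")
  shown <- x$exclusions[x$exclusions$n > 0, ]
  if (nrow(shown) > 0) {
    cat("  excluded by rule:\n")
    for (i in seq_len(nrow(shown))) {
      cat(sprintf("    %-15s %d\n", shown$rule_id[i], shown$n[i]))
    }
  }
  invisible(x)
}

#' Polypharmacy flag
#'
#' A report is a polypharmacy report when the patient was using five or more
#' medications concurrently.
#'
#' @param n_medications Positive integer (vectorised); `NA` propagates.
#' @return Logical: `TRUE` iff `n_medications >= 5`.
#' @export
flag_polypharmacy <- function(n_medications) {
  if (any(!is.na(n_medications) & n_medications < 1)) {
    stop("`n_medications` must be >= 1", call. = FALSE)
  }
  n_medications >= 5
}

#' Dichotomise the impact-on-primary-disease outcome
#'
#' Reports where the ADR prolonged or worsened the primary disease, left
#' sequelae, or ended in death are coded `"effect"`; all other reports are
#' `"no_effect"`.
#'
#' @param impact Character vector over the impact levels
#'   (`r paste(IMPACT_LEVELS, collapse = ", ")`); `NA` propagates.
#' @return Character vector over `c("effect", "no_effect")`.
#' @export
dichotomize_impact <- function(impact) {
  bad <- !is.na(impact) & !(impact %in% IMPACT_LEVELS)
  if (any(bad)) {
    stop("invalid impact label(s): ", paste(unique(impact[bad]), collapse = ", "),
         call. = FALSE)
  }
  ifelse(is.na(impact), NA_character_,
         ifelse(impact == "no_effect", "no_effect", "effect"))
}

#' Bin the ADR onset time
#'
#' Days from the start of medication (day of first administration = 0) to
#' ADR onset, partitioned into same-day, 1-3, 4-7, 8-30 and >30 day bins --
#' a total, order-preserving partition of the non-negative integers.
#'
#' @param onset_days Non-negative integer vector; `NA` propagates.
#' @return Factor with levels `r paste(ONSET_BINS, collapse = ", ")`.
#' @export
bin_onset <- function(onset_days) {
  if (any(!is.na(onset_days) & onset_days < 0)) {
    stop("`onset_days` must be non-negative (negative onsets are excluded upstream)",
         call. = FALSE)
  }
  cut(onset_days, breaks = c(-0.5, 0.5, 3.5, 7.5, 30.5, Inf),
      labels = ONSET_BINS)
}

#' Age group coding
#'
#' Age in whole years mapped to the groups 0-5, 6-17, 18-34, 35-59, 60-79
#' and >=80; boundary ages belong to the younger-labelled group exactly as
#' the labels state.
#'
#' @param age Non-negative integer vector; `NA` propagates.
#' @return Factor with levels `r paste(AGE_GROUPS, collapse = ", ")`.
#' @export
age_group <- function(age) {
  if (any(!is.na(age) & age < 0)) stop("`age` must be non-negative", call. = FALSE)
  cut(age, breaks = c(-0.5, 5.5, 17.5, 34.5, 59.5, 79.5, Inf),
      labels = AGE_GROUPS)
}
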