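# End-to-end orchestration: filter -> describe -> regress -> stratify ->
# signals, with deterministic CSV outputs and a hashed manifest.

#' Pipeline configuration
#'
#' @param input Path to a report CSV, or `NULL` to simulate.
#' @param sim Optional [sim_config()] used when `input` is `NULL`.
#' @param outdir Output directory (created if needed).
#' @param alpha Significance level carried in the run metadata (0 < alpha < 1).
#' @param signal_rule `"intersection"` or `"union"` (see [evaluate_signal()]).
#' @param prr_se `"printed"` or `"textbook"` PRR standard error.
#' @param seed Integer seed (used when simulating).
#' @param dialect Optional column-name map passed to [parse_reports()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, sim = NULL, outdir = tempfile("srs_run_"),
                            alpha = 0.05, signal_rule = "intersection",
                            prr_se = "printed", seed = 1L, dialect = NULL) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(list(input = input, sim = sim, outdir = outdir, alpha = alpha,
                 signal_rule = signal_rule, prr_se = prr_se,
                 seed = as.integer(seed), dialect = dialect),
            class = "pipeline_config")
}

#' Write a stage output table in the published rendering style
#'
#' CSV with fixed column order and fixed decimal rendering: percentage
#' columns (`pct*`) at two decimals, odds ratios / CI limits / chi-square
#' values at two decimals, and p-values as a raw numeric column plus a
#' display column using the `"<0.001"` floor and `"NE"` for not-evaluated
#' entries.
#'
#' @param table Data frame or tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  out <- tibble::as_tibble(table)
  two_dp <- function(x) ifelse(is.na(x), "NE", sprintf("%.2f", round_half_away(x, 2L)))
  for (col in names(out)) {
    if (grepl("^(pct|or|ci_low|ci_high|ror|prr|chi2)", col) ||
        grepl("(^|_)(or|ror|prr|chi2|pct|ci_low|ci_high)(_|$)", col)) {
      if (is.numeric(out[[col]])) out[[col]] <- two_dp(out[[col]])
    }
  }
  if ("p_value" %in% names(out)) {
    out$p_display <- format_p(out$p_value)
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(out, path, progress = FALSE, na = "NE")
  invisible(path)
}

crosstab_as_rows <- function(ct, block) {
  tib <- tibble::tibble(
    block = block,
    level = rep(rownames(ct$counts), ncol(ct$counts)),
    column = rep(colnames(ct$counts), each = nrow(ct$counts)),
    n = as.integer(ct$counts),
    pct = as.numeric(ct$percents)
  )
  tib$p_value <- ifelse(seq_len(nrow(tib)) == 1, ct$test$p_value, NA_real_)
  tib$test <- ifelse(seq_len(nrow(tib)) == 1, ct$test$method, NA_character_)
  tib
}

#' Run the full analysis pipeline
#'
#' Stages: load (or simulate) -> inclusion filtering -> descriptive tables
#' (demographics, SOC by drug class, severity/impact, SOC by patent status,
#' onset distribution) -> logistic models for severity and impact ->
#' stratified Mantel-Haenszel ORs -> disproportionality signals. Each stage
#' writes a CSV to `config$outdir`; a manifest with an MD5 content hash per
#' file is written last, so identical config + seed yields identical
#' hashes.
#'
#' @param config A [pipeline_config()].
#' @return Tibble manifest (file, md5), invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()

  reports <- if (!is.null(cfg$input)) {
    if (!file.exists(cfg$input)) {
      stop("stage load: input file not found: ", cfg$input, call. = FALSE)
    }
    parse_reports(cfg$input, dialect = cfg$dialect)
  } else {
    sim <- if (is.null(cfg$sim)) sim_config(seed = cfg$seed) else cfg$sim
    sim$seed <- cfg$seed
    generate_reports(sim)
  }

  filt <- apply_inclusion_filters(reports)
  retained <- filt$retained
  files["filtered"] <- file.path(cfg$outdir, "filtered.csv")
  write_reports(retained, files[["filtered"]])
  files["exclusions"] <- file.path(cfg$outdir, "exclusions.csv")
  readr::write_csv(filt$log$exclusion_log, files[["exclusions"]], progress = FALSE)

  demo <- dplyr::bind_rows(lapply(
    c("age_group", "sex", "year", "disease_type", "polypharmacy",
      "past_adr_history"),
    function(v) crosstab_as_rows(crosstab(retained, v, "drug_class"), v)
  ))
  files["table_demographics"] <- file.path(cfg$outdir, "table_demographics.csv")
  write_table(demo, files[["table_demographics"]])

  files["table_soc"] <- file.path(cfg$outdir, "table_soc.csv")
  write_table(soc_table(retained, "drug_class"), files[["table_soc"]])

  sev <- dplyr::bind_rows(
    crosstab_as_rows(crosstab(retained, "severity", "drug_class"), "severity"),
    crosstab_as_rows(crosstab(retained, "impact", "drug_class"), "impact")
  )
  files["table_severity"] <- file.path(cfg$outdir, "table_severity.csv")
  write_table(sev, files[["table_severity"]])

  if (any(retained$drug_class == "mab")) {
    files["table_patent"] <- file.path(cfg$outdir, "table_patent.csv")
    write_table(soc_table(retained, "patent_status"), files[["table_patent"]])
  }

  od <- onset_distribution(retained)
  files["onset"] <- file.path(cfg$outdir, "onset.csv")
  write_table(od$table, files[["onset"]])

  for (oc in c("severity", "impact")) {
    fit <- tryCatch(fit_logistic(retained, outcome = oc),
                    error = function(e) NULL)
    if (is.null(fit)) next
    tab <- tibble::as_tibble(fit)
    tab$converged <- attr(fit, "converged")
    key <- paste0("regress_", oc)
    files[key] <- file.path(cfg$outdir, paste0(key, ".csv"))
    write_table(tab, files[[key]])
  }

  strat <- dplyr::bind_rows(lapply(
    c("sex", "age_group", "disease_type", "polypharmacy", "past_adr_history"),
    function(v) {
      s <- stratified_mab_effect(retained, v)
      s$strata$variable <- v
      s$strata$mh_pooled_or <- s$pooled$or
      s$strata
    }
  ))
  files["stratified"] <- file.path(cfg$outdir, "stratified.csv")
  write_table(strat, files[["stratified"]])

  metrics <- evaluate_signal(build_dec_tables(retained), rule = cfg$signal_rule,
                             prr_se = cfg$prr_se)
  files["signals"] <- file.path(cfg$outdir, "signals.csv")
  write_table(rank_signals(metrics), files[["signals"]])

  manifest <- tibble::tibble(
    file = basename(unname(files)),
    md5 = unname(tools::md5sum(unname(files)))
  )
  readr::write_csv(manifest, file.path(cfg$outdir, "manifest.csv"), progress = FALSE)
  invisible(manifest)
}
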