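# Descriptive comparison: crosstabulations with column percentages,
# chi-square / Fisher exact tests, onset-time distributions and SOC tables.

#' Uncorrected Pearson chi-square test on an r x c count table
#'
#' Plain Pearson X-squared = sum (O-E)^2 / E with df = (r-1)(c-1) and the
#' upper-tail chi-square p-value. No continuity correction is applied here;
#' the Yates correction is used only inside the MHRA signal statistic
#' ([mhra_chi2()]). Zero-margin rows/columns are dropped before testing,
#' with a warning.
#'
#' @param table Integer matrix of counts.
#' @return List with `statistic`, `df`, `p_value`, `method = "chi2"`.
#' @export
pearson_chi2_test <- function(table) {
  table <- as.matrix(table)
  keep_r <- rowSums(table) > 0
  keep_c <- colSums(table) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("zero-margin row(s)/column(s) dropped before chi-square test",
            call. = FALSE)
    table <- table[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(table) < 2 || ncol(table) < 2) {
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                method = "NE"))
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), method = "chi2")
}

#' Two-sided Fisher exact test on a 2 x 2 count table
#'
#' The two-sided p-value sums the hypergeometric probabilities of all tables
#' with the observed margins whose probability does not exceed that of the
#' observed table.
#'
#' @param table 2 x 2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) {
    stop("`table` must be 2 x 2", call. = FALSE)
  }
  stats::fisher.test(table)$p.value
}

#' Choose between chi-square and Fisher exact for a 2 x 2 table
#'
#' Standard practice: Fisher's exact test whenever any expected cell count
#' is below 5, otherwise the (uncorrected) chi-square test.
#'
#' @param table 2 x 2 matrix of counts.
#' @return `"fisher"` or `"chi2"`.
#' @export
choose_test <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("`table` must be 2 x 2", call. = FALSE)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected < 5)) "fisher" else "chi2"
}

run_2x2_test <- function(table) {
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                method = "NE"))
  }
  if (choose_test(table) == "fisher") {
    list(statistic = NA_real_, df = NA_real_,
         p_value = fisher_exact_2x2(table), method = "fisher")
  } else {
    pearson_chi2_test(table)
  }
}

#' Crosstabulate two report variables with column percentages
#'
#' Counts and column percentages (two decimals, [percent()]) of `row_var` by
#' `col_var`. Reports with a missing or `"unknown"` value in either variable
#' are dropped from this table only. The attached test is chosen by
#' [choose_test()] for 2 x 2 tables and is the uncorrected Pearson
#' chi-square otherwise; degenerate tables (fewer than two non-empty rows or
#' columns) carry test `"NE"`.
#'
#' @param reports Report tibble.
#' @param row_var,col_var Column names; derived variables `"age_group"`,
#'   `"onset_bin"`, `"disease_type"`, `"polypharmacy"` and `"impact2"` are
#'   also accepted.
#' @return A `crosstab`: list with `counts` (matrix), `percents` (matrix),
#'   `row_var`, `col_var` and `test` (statistic, df, p_value, method).
#' @export
crosstab <- function(reports, row_var, col_var) {
  rv <- derived_var(reports, row_var)
  cv <- derived_var(reports, col_var)
  keep <- !is.na(rv) & !is.na(cv) & rv != "unknown" & cv != "unknown"
  rv <- factor(rv[keep], levels = var_levels(rv[keep]))
  cv <- factor(cv[keep], levels = var_levels(cv[keep]))
  counts <- unclass(table(rv, cv))
  names(dimnames(counts)) <- NULL
  pct <- counts
  for (j in seq_len(ncol(counts))) {
    tot <- sum(counts[, j])
    pct[, j] <- if (tot > 0) percent(counts[, j], tot) else NA_real_
  }
  nonempty_r <- sum(rowSums(counts) > 0)
  nonempty_c <- sum(colSums(counts) > 0)
  test <- if (nonempty_r < 2 || nonempty_c < 2) {
    list(statistic = NA_real_, df = NA_real_, p_value = NA_real_, method = "NE")
  } else if (all(dim(counts) == c(2L, 2L))) {
    run_2x2_test(counts)
  } else {
    pearson_chi2_test(counts)
  }
  structure(list(counts = counts, percents = pct, row_var = row_var,
                 col_var = col_var, test = test),
            class = "crosstab")
}

# derived categorical views over the canonical columns
derived_var <- function(reports, var) {
  switch(var,
    age_group    = as.character(age_group(reports$age)),
    onset_bin    = as.character(bin_onset(reports$onset_days)),
    disease_type = ifelse(is.na(reports$n_diseases), NA_character_,
                          ifelse(reports$n_diseases > 1, "multiple", "single")),
    polypharmacy = ifelse(flag_polypharmacy(reports$n_medications),
                          "polypharmacy", "non_polypharmacy"),
    impact2      = dichotomize_impact(reports$impact),
    past_adr_history = ifelse(reports$past_adr_history, "yes", "no"),
    {
      if (!var %in% names(reports)) stop("unknown variable: ", var, call. = FALSE)
      as.character(reports[[var]])
    }
  )
}

# stable display order for the levels of known enums; data order otherwise
var_levels <- function(x) {
  known <- list(SEVERITY_LEVELS, IMPACT_LEVELS, DRUG_CLASSES, AGE_GROUPS,
                ONSET_BINS, c("single", "multiple"),
                c("polypharmacy", "non_polypharmacy"),
                c("effect", "no_effect"), c("no", "yes"),
                c("female", "male"), PATENT_LEVELS, 2016:2020)
  for (lv in known) {
    if (all(x %in% lv)) return(as.character(lv[lv %in% x]))
  }
  sort(unique(x))
}

#' @export
print.crosstab <- function(x, ...) {
  cat(x$row_var, "x", x$col_var, "\n")
  disp <- matrix(sprintf("%d (%.2f)", x$counts, x$percents),
                 nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  print(disp, quote = FALSE)
  if (x$test$method == "NE") {
    cat("test: NE\n")
  } else {
    cat(sprintf("test: %s, p %s\n", x$test$method, format_p(x$test$p_value)))
  }
  invisible(x)
}

#' Onset-time distribution by drug class
#'
#' Counts and percentages of reports per onset bin ([bin_onset()]) within
#' each drug class. Reports with missing onset are dropped from this table
#' and counted in `n_missing`; denominators are per drug class among
#' known-onset reports.
#'
#' @param reports Report tibble.
#' @return List with `table` (tibble: drug_class, onset_bin, n, pct) and
#'   `n_missing`.
#' @export
onset_distribution <- function(reports) {
  known <- reports[!is.na(reports$onset_days), ]
  n_missing <- nrow(reports) - nrow(known)
  if (nrow(known) == 0) {
    return(list(table = tibble::tibble(drug_class = character(),
                                       onset_bin = character(),
                                       n = integer(), pct = numeric()),
                n_missing = n_missing))
  }
  tab <- known |>
    dplyr::mutate(onset_bin = bin_onset(.data$onset_days)) |>
    dplyr::count(.data$drug_class, .data$onset_bin, .drop = FALSE) |>
    dplyr::group_by(.data$drug_class) |>
    dplyr::mutate(pct = percent(.data$n, sum(.data$n))) |>
    dplyr::ungroup() |>
    dplyr::mutate(onset_bin = as.character(.data$onset_bin))
  list(table = tab, n_missing = n_missing)
}

#' System-organ-class table split by drug class or patent status
#'
#' One row per SOC present in `reports`, with counts and column percentages
#' per split level, sorted by total count descending. Each row carries a
#' 2 x 2-vs-rest test (chi-square or Fisher via [choose_test()]); rows with
#' a zero cell in their own counts are marked `"NE"` (not evaluated).
#'
#' @param reports Report tibble.
#' @param split_var `"drug_class"` or `"patent_status"`. For
#'   `"patent_status"` the table is computed within mAb reports (branded vs
#'   biosimilar).
#' @return Tibble with columns `soc`, `n_<level>`, `pct_<level>` per level,
#'   `p_value`, `test`.
#' @export
soc_table <- function(reports, split_var = c("drug_class", "patent_status")) {
  split_var <- match.arg(split_var)
  if (split_var == "patent_status") {
    reports <- reports[reports$drug_class == "mab", ]
    levels <- c("branded", "biosimilar")
  } else {
    levels <- DRUG_CLASSES
  }
  split <- factor(reports[[split_var]], levels = levels)
  keep <- !is.na(split)
  counts <- unclass(table(factor(reports$soc[keep]), split[keep]))
  counts <- counts[order(-rowSums(counts), rownames(counts)), , drop = FALSE]
  col_tot <- colSums(counts)

  out <- tibble::tibble(soc = rownames(counts))
  for (j in seq_along(levels)) {
    out[[paste0("n_", levels[j])]] <- unname(counts[, j])
    out[[paste0("pct_", levels[j])]] <- percent(unname(counts[, j]), col_tot[j])
  }
  p <- rep(NA_real_, nrow(counts))
  meth <- rep("NE", nrow(counts))
  for (i in seq_len(nrow(counts))) {
    if (any(counts[i, ] == 0)) next
    t22 <- rbind(counts[i, ], col_tot - counts[i, ])
    res <- run_2x2_test(t22)
    p[i] <- res$p_value
    meth[i] <- res$method
  }
  out$p_value <- p
  out$test <- meth
  out
}
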