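# Deficiency classification against the cutoff table and production of the
# two output artifacts (cleaned per-participant CSVs, summary CSV).

participant_age_months <- function(ds) {
  if ("age_months" %in% names(ds$data)) ds$data$age_months
  else if ("age_years" %in% names(ds$data)) ds$data$age_years * 12
  else rep(NA_real_, nrow(ds$data))
}

#' Classify deficiency per participant
#'
#' Matches each participant against every applicable cutoff rule (same
#' biomarker; rule group equal to the dataset's population group or `any`;
#' rule sex equal to the participant's sex or `any`; age inside the rule's
#' closed age range).  Comparison is strict: a value exactly at the
#' threshold is not deficient.  A rule with `use_adjusted = TRUE` is
#' evaluated on the inflammation-adjusted value when adjustment ran, else
#' on the unadjusted value.  Missing values, missing adjusted values, or no
#' matching rule yield a missing call.
#'
#' @param ds A SI-converted `std_dataset`.
#' @param adjustment An `adjustment_result` from [adjust_dataset()], or
#'   `NULL` when the adjustment step was skipped.
#' @param cutoffs A `cutoff_table`.
#' @return A `deficiency_calls` data frame with columns `row_id`,
#'   `biomarker`, `condition_label`, `deficient` (0/1/NA), `value_used`,
#'   `threshold`, `adjusted` (whether the adjusted value was used).
#' @export
classify_deficiency <- function(ds, adjustment = NULL, cutoffs) {
  stopifnot(inherits(ds, "std_dataset"), inherits(cutoffs, "cutoff_table"))
  if (!isTRUE(ds$si_converted))
    mn_validation_error("classify_deficiency requires an SI-converted dataset")
  n <- nrow(ds$data)
  grp <- ds$descriptor$population_group %||% "other"
  sex <- if ("sex" %in% names(ds$data)) ds$data$sex else rep(NA_character_, n)
  age_m <- participant_age_months(ds)
  adj_ran <- !is.null(adjustment) && !adjustment$bypassed
  out <- list()
  rules <- cutoffs[cutoffs$biomarker %in% names(ds$units), , drop = FALSE]
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    grp_ok <- r$group == "any" | r$group == grp
    if (!grp_ok) next
    sex_ok <- r$sex == "any" | (!is.na(sex) & sex == r$sex)
    lim <- rule_age_months(r)
    age_ok <- !is.na(age_m) & age_m >= lim[1, "lo"] & age_m <= lim[1, "hi"]
    use_adj <- r$use_adjusted && adj_ran &&
      paste0(r$biomarker, "_adj") %in% names(adjustment$adjusted)
    match_ok <- sex_ok & age_ok
    one_version <- function(value, adjusted, primary) {
      def <- rep(NA_real_, n)
      hit <- match_ok & !is.na(value)
      def[hit] <- if (r$direction == "below")
        as.numeric(value[hit] < r$threshold)
      else as.numeric(value[hit] > r$threshold)
      data.frame(
        row_id = ds$data$row_id, biomarker = r$biomarker,
        condition_label = r$condition_label, deficient = def,
        value_used = ifelse(match_ok, value, NA_real_),
        threshold = r$threshold, adjusted = adjusted, primary = primary,
        stringsAsFactors = FALSE)
    }
    value <- if (use_adj) adjustment$adjusted[[paste0(r$biomarker, "_adj")]]
      else ds$data[[r$biomarker]]
    out[[length(out) + 1L]] <- one_version(value, use_adj, TRUE)
    # comparison copy on the unadjusted scale when the rule used adjusted values
    if (use_adj)
      out[[length(out) + 1L]] <- one_version(ds$data[[r$biomarker]], FALSE, FALSE)
  }
  calls <- if (length(out)) do.call(rbind, out) else data.frame(
    row_id = integer(), biomarker = character(), condition_label = character(),
    deficient = numeric(), value_used = numeric(), threshold = numeric(),
    adjusted = logical(), primary = logical(), stringsAsFactors = FALSE)
  # non-overlap of rules guarantees at most one call per (row, condition)
  structure(calls, class = c("deficiency_calls", "data.frame"))
}

dataset_design <- function(ds) {
  d <- ds$data
  svy_design(n = nrow(d),
             stratum = if ("stratum" %in% names(d)) d$stratum,
             cluster = if ("cluster" %in% names(d)) d$cluster,
             weight = if ("weight" %in% names(d)) d$weight)
}

summary_row <- function(dataset_id, biomarker, condition_label, est, adjusted,
                        cutoff = NA_real_) {
  data.frame(dataset_id = dataset_id, biomarker = biomarker,
             condition_label = condition_label, statistic = est$statistic,
             estimate = est$estimate, se = est$se, ci_low = est$ci_low,
             ci_high = est$ci_high, n = est$n, n_weighted = est$n_weighted,
             adjusted = adjusted, cutoff_used = cutoff,
             stringsAsFactors = FALSE)
}

#' Design-based summary statistics for a dataset
#'
#' For each biomarker: arithmetic mean, geometric mean and the 25th, 50th
#' and 75th percentiles of the analysis value — the adjusted value when
#' adjustment ran (rows whose adjustment is unavailable are excluded
#' complete-case), with unadjusted duplicates flagged `adjusted = FALSE`.
#' For each condition with classification calls: prevalence in percent.
#' All estimates go through the survey engine with the dataset's declared
#' design (SRS with unit weights when none is declared).
#'
#' @param ds A SI-converted `std_dataset`.
#' @param adjustment An `adjustment_result` or `NULL`.
#' @param calls A `deficiency_calls` data frame from [classify_deficiency()].
#' @param statistics Distribution statistics to compute.
#' @param lonely Lonely-PSU handling passed to the estimators.
#' @return A `summary_table` data frame, one row per (biomarker, statistic,
#'   adjusted) and per (condition, adjusted).
#' @export
summarize_dataset <- function(ds, adjustment = NULL, calls = NULL,
                              statistics = c("mean", "geometric_mean",
                                             "q25", "median", "q75"),
                              lonely = c("error", "centered")) {
  stopifnot(inherits(ds, "std_dataset"))
  lonely <- match.arg(lonely)
  design <- dataset_design(ds)
  adj_ran <- !is.null(adjustment) && !adjustment$bypassed
  rows <- list()
  emit <- function(row) rows[[length(rows) + 1L]] <<- row
  stat_fun <- function(values, stat) {
    switch(stat,
      mean = svy_mean(values, design, lonely = lonely),
      geometric_mean = svy_geomean(values, design, lonely = lonely),
      q25 = svy_quantile(values, design, p = 0.25, lonely = lonely),
      median = svy_quantile(values, design, p = 0.5, lonely = lonely),
      q75 = svy_quantile(values, design, p = 0.75, lonely = lonely),
      mn_validation_error(sprintf("unknown statistic '%s'", stat)))
  }
  for (bm in names(ds$units)) {
    versions <- list(list(values = ds$data[[bm]], adjusted = FALSE))
    if (adj_ran && paste0(bm, "_adj") %in% names(adjustment$adjusted))
      versions <- c(list(list(values = adjustment$adjusted[[paste0(bm, "_adj")]],
                              adjusted = TRUE)), versions)
    for (v in versions) {
      if (all(is.na(v$values))) {
        warning(sprintf("dataset '%s': biomarker '%s'%s has no non-missing values; omitted",
                        ds$dataset_id, bm, if (v$adjusted) " (adjusted)" else ""))
        next
      }
      for (st in statistics)
        emit(summary_row(ds$dataset_id, bm, "distribution",
                         stat_fun(v$values, st), v$adjusted))
    }
  }
  if (!is.null(calls) && nrow(calls)) {
    key <- unique(calls[, c("biomarker", "condition_label", "adjusted",
                            "threshold")])
    for (i in seq_len(nrow(key))) {
      k <- key[i, ]
      sel <- calls$biomarker == k$biomarker &
        calls$condition_label == k$condition_label &
        calls$adjusted == k$adjusted
      ind <- calls$deficient[sel][order(calls$row_id[sel])]
      if (all(is.na(ind))) {
        warning(sprintf(
          "dataset '%s': condition '%s' has no classifiable participants; omitted",
          ds$dataset_id, k$condition_label))
        next
      }
      emit(summary_row(ds$dataset_id, k$biomarker, k$condition_label,
                       svy_prevalence(ind, design, lonely = lonely),
                       k$adjusted, cutoff = k$threshold))
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else data.frame()
  structure(tab, class = c("summary_table", "data.frame"))
}

#' Write the cleaned per-participant dataset
#'
#' CSV with standardized variable names and SI units, unadjusted and (when
#' adjustment ran) `_adj`-suffixed adjusted biomarker columns, per-row
#' provenance flags (`zero_recoded_*`, `*_not_adjusted`) and one
#' `def_<condition>` column per classified condition.  Metadata (units,
#' adjustment bypass reason) is written as leading `#` comment lines; read
#' the file back with `comment.char = "#"`.
#'
#' @param ds A SI-converted `std_dataset`.
#' @param adjustment An `adjustment_result` or `NULL`.
#' @param calls A `deficiency_calls` data frame or `NULL`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_clean_dataset <- function(ds, adjustment = NULL, calls = NULL, path) {
  stopifnot(inherits(ds, "std_dataset"))
  out <- ds$data
  adj_ran <- !is.null(adjustment) && !adjustment$bypassed
  if (adj_ran) {
    out <- merge(out, adjustment$adjusted, by = "row_id", sort = FALSE)
    fl <- adjustment$not_adjusted
    if (ncol(fl) > 1L) out <- merge(out, fl, by = "row_id", sort = FALSE)
  }
  if (ncol(ds$flags) > 1L) out <- merge(out, ds$flags, by = "row_id", sort = FALSE)
  if (!is.null(calls) && nrow(calls)) {
    calls <- calls[calls$primary %||% TRUE, , drop = FALSE]
    for (cond in unique(calls$condition_label)) {
      sub <- calls[calls$condition_label == cond, ]
      v <- rep(NA_real_, nrow(out))
      v[match(sub$row_id, out$row_id)] <- sub$deficient
      out[[paste0("def_", cond)]] <- v
    }
  }
  out <- out[order(out$row_id), , drop = FALSE]
  meta <- c(
    sprintf("# dataset_id: %s", ds$dataset_id),
    sprintf("# units: %s", paste(names(ds$units), ds$units, sep = "=",
                                 collapse = "; ")),
    if (!is.null(adjustment) && adjustment$bypassed)
      sprintf("# inflammation_adjustment: bypassed (%s)", adjustment$reason)
    else if (adj_ran) "# inflammation_adjustment: BRINDA regression correction"
    else "# inflammation_adjustment: not requested")
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) mn_io_error(sprintf(
                    "cannot write clean dataset to '%s': %s", path,
                    conditionMessage(e))))
  on.exit(close(con))
  writeLines(meta, con)
  is_num <- vapply(out, is.numeric, logical(1))
  ser <- out
  for (j in which(is_num)) ser[[j]] <- fmt_num(out[[j]])
  utils::write.csv(ser, con, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read back a cleaned dataset written by [write_clean_dataset()]
#' @param path CSV path.
#' @return Data frame with numeric columns restored.
#' @export
read_clean_dataset <- function(path) {
  if (!file.exists(path)) mn_io_error(sprintf("file not found: %s", path))
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write the cross-dataset summary CSV
#'
#' One file across all datasets, fixed column order (`dataset_id`,
#' `biomarker`, `condition_label`, `statistic`, `estimate`, `se`, `ci_low`,
#' `ci_high`, `n`, `n_weighted`, `adjusted`, `cutoff_used`), full-precision
#' serialization plus rounded display columns (`estimate_display` etc.).
#' Absent SEs are empty cells, not zeros.
#'
#' @param rows A `summary_table` (rows from one or more datasets).
#' @param path Output CSV path.
#' @param display_digits Decimals for the display columns.
#' @return `path`, invisibly.
#' @export
write_summary_report <- function(rows, path, display_digits = 2) {
  if (is.null(rows) || nrow(rows) == 0L)
    mn_validation_error("summary report requires at least one row")
  cols <- c("dataset_id", "biomarker", "condition_label", "statistic",
            "estimate", "se", "ci_low", "ci_high", "n", "n_weighted",
            "adjusted", "cutoff_used")
  rows <- rows[, cols]
  o <- order(rows$dataset_id, rows$biomarker, rows$condition_label,
             !rows$adjusted, match(rows$statistic,
               c("mean", "geometric_mean", "q25", "median", "q75", "prevalence")))
  rows <- rows[o, , drop = FALSE]
  ser <- rows
  for (col in c("estimate", "se", "ci_low", "ci_high", "n_weighted", "cutoff_used"))
    ser[[col]] <- fmt_num(rows[[col]])
  for (col in c("estimate", "se", "ci_low", "ci_high"))
    ser[[paste0(col, "_display")]] <- ifelse(
      is.na(rows[[col]]), "",
      formatC(round(rows[[col]], display_digits),
              format = "f", digits = display_digits))
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) mn_io_error(sprintf(
                    "cannot write summary report to '%s': %s", path,
                    conditionMessage(e))))
  on.exit(close(con))
  utils::write.csv(ser, con, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read back a summary report written by [write_summary_report()]
#' @param path CSV path.
#' @return Data frame with numeric columns restored.
#' @export
read_summary_report <- function(path) {
  if (!file.exists(path)) mn_io_error(sprintf("file not found: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("estimate", "se", "ci_low", "ci_high", "n_weighted", "cutoff_used"))
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  tab
}
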