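# End-to-end pipeline: templates -> ingest -> units -> adjustment ->
# classification -> design-based summaries -> output files.

#' Run the full analysis pipeline
#'
#' Executes, for each of the first `n_datasets` columns of the dataset
#' template: load, pre-analysis error checking, standardization, zero
#' recode, SI conversion, BRINDA inflammation adjustment (bypassed with a
#' logged reason when inapplicable), deficiency classification against the
#' cutoff table, and design-based summary statistics.  Writes one cleaned
#' CSV per dataset (`<output_name>_<dataset_id>_clean.csv`) and a single
#' summary CSV across datasets (`<output_name>_summary.csv`), plus a run
#' log (`<output_name>_log.txt`).  A dataset failing validation is
#' reported and skipped; the remaining datasets still run.
#'
#' @param data_template Path to the dataset-descriptor template.
#' @param cutoff_template Path to the cutoff template (default: the
#'   packaged table).
#' @param n_datasets Number of template columns to process, or `"all"`.
#' @param output_dir Output directory (created if needed).
#' @param output_name Base name for output files.
#' @param adjust An [adjust_config()].
#' @param registry A conversion registry; extend it with
#'   [register_conversion()] for user-added biomarkers/units.
#' @param missing_codes Sentinel strings treated as missing on ingest.
#' @param lonely Lonely-PSU handling for variance estimation.
#' @param statistics Distribution statistics to report.
#' @return A `pipeline_result`: list with `datasets` (per-dataset status,
#'   clean-file path or error message), `summary` (the combined
#'   `summary_table`), `summary_path`, `log_path`, `log`, `n_failed`.
#' @export
run_pipeline <- function(data_template,
                         cutoff_template = default_cutoff_path(),
                         n_datasets = "all",
                         output_dir,
                         output_name = "mnsurvey",
                         adjust = adjust_config(),
                         registry = si_registry(),
                         missing_codes = character(),
                         lonely = c("error", "centered"),
                         statistics = c("mean", "geometric_mean",
                                        "q25", "median", "q75")) {
  lonely <- match.arg(lonely)
  if (!dir.exists(output_dir))
    if (!dir.create(output_dir, recursive = TRUE))
      mn_io_error(sprintf("cannot create output directory '%s'", output_dir))
  log_lines <- character(0)
  log <- function(...) log_lines <<- c(log_lines, sprintf(...))

  descriptors <- load_dataset_template(data_template, registry)
  cutoffs <- load_cutoff_template(cutoff_template, registry)
  log("loaded %d dataset descriptor(s) from %s", length(descriptors),
      data_template)
  log("loaded %d cutoff rule(s) from %s", nrow(cutoffs), cutoff_template)
  vrep <- validate_templates(descriptors, cutoffs)
  for (i in seq_len(nrow(vrep)))
    log("template check [%s] %s %s: %s", vrep$severity[i], vrep$dataset_id[i],
        vrep$field[i], vrep$message[i])

  if (!identical(n_datasets, "all")) {
    k <- as.integer(n_datasets)
    if (is.na(k) || k < 1L || k > length(descriptors))
      mn_validation_error(sprintf(
        "n_datasets must be 'all' or an integer in 1..%d", length(descriptors)))
    descriptors <- descriptors[seq_len(k)]
  }

  all_summaries <- list()
  results <- list()
  for (d in descriptors) {
    id <- d$dataset_id
    res <- tryCatch({
      withCallingHandlers({
        raw <- load_raw(d)
        rep <- check_errors(raw, d)
        for (i in seq_len(nrow(rep$items)))
          log("dataset %s: [%s] %s: %s", id, rep$items$severity[i],
              rep$items$field[i], rep$items$message[i])
        if (rep$is_fatal)
          mn_validation_error(sprintf(
            "dataset '%s' failed pre-analysis checks; correct the items above", id))
        ds <- standardize(raw, d, missing_codes)
        ds <- recode_zeros(ds)
        nz <- sum(vapply(ds$flags[grep("^zero_recoded_", names(ds$flags))],
                         sum, numeric(1)))
        if (nz > 0) log("dataset %s: %d zero value(s) recoded to 0.0001", id, nz)
        ds <- convert_to_si(ds, registry)
        adj <- adjust_dataset(ds, adjust)
        if (adj$bypassed)
          log("dataset %s: inflammation adjustment bypassed: %s", id, adj$reason)
        else
          log("dataset %s: adjusted %s", id,
              paste(names(adj$models)[!vapply(adj$models, `[[`, logical(1),
                                              "bypassed")], collapse = ", "))
        calls <- classify_deficiency(ds, adj, cutoffs)
        summ <- summarize_dataset(ds, adj, calls, statistics, lonely)
        clean_path <- file.path(output_dir,
                                sprintf("%s_%s_clean.csv", output_name, id))
        write_clean_dataset(ds, adj, calls, clean_path)
        log("dataset %s: wrote %s", id, clean_path)
        list(status = "ok", clean_path = clean_path, summary = summ)
      }, warning = function(w) {
        log("dataset %s: warning: %s", id, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    }, mn_error = function(e) {
      log("dataset %s: FAILED: %s", id, conditionMessage(e))
      list(status = "failed", error = conditionMessage(e))
    })
    results[[id]] <- res
    if (res$status == "ok") all_summaries[[id]] <- res$summary
  }

  summary_path <- NULL
  summary_tab <- NULL
  if (length(all_summaries)) {
    summary_tab <- do.call(rbind, all_summaries)
    rownames(summary_tab) <- NULL
    class(summary_tab) <- c("summary_table", "data.frame")
    summary_path <- file.path(output_dir, sprintf("%s_summary.csv", output_name))
    write_summary_report(summary_tab, summary_path)
    log("wrote %s", summary_path)
  } else {
    log("no dataset completed; summary not written")
  }
  n_failed <- sum(vapply(results, function(r) r$status == "failed", logical(1)))
  log_path <- file.path(output_dir, sprintf("%s_log.txt", output_name))
  writeLines(log_lines, log_path)
  structure(list(datasets = results, summary = summary_tab,
                 summary_path = summary_path, log_path = log_path,
                 log = log_lines, n_failed = n_failed),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d dataset(s), %d failed\n",
              length(x$datasets), x$n_failed))
  for (id in names(x$datasets)) {
    r <- x$datasets[[id]]
    cat(sprintf("  %s: %s%s\n", id, r$status,
                if (r$status == "failed") paste0(" (", r$error, ")") else ""))
  }
  if (!is.null(x$summary_path)) cat("  summary:", x$summary_path, "\n")
  cat("  log:", x$log_path, "\n")
  invisible(x)
}
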