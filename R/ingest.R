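# Loading, error checking and standardization of participant-level data
# (pipeline steps: load, check, standardize names, recode zeros).

detect_format <- function(path, declared = "auto") {
  if (declared != "auto") return(declared)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = "csv", xlsx = "excel", xls = "excel",
    sas7bdat = "sas", xpt = "sas", sav = "spss", dta = "stata",
    mn_validation_error(sprintf(
      "cannot auto-detect the format of '%s'; declare it in the template", path)))
}

strip_haven_attrs <- function(df) {
  as.data.frame(lapply(df, function(x) {
    if (inherits(x, "haven_labelled")) x <- haven::zap_labels(x)
    attributes(x) <- NULL
    x
  }), stringsAsFactors = FALSE, check.names = FALSE)
}

#' Load a raw participant-level dataset
#'
#' Reads the file named by a descriptor in its declared (or auto-detected)
#' format.  All columns are preserved verbatim; no renaming, recoding or
#' unit handling happens at this stage.
#'
#' @param descriptor A [dataset_descriptor()].
#' @return A `raw_dataset`: list with `dataset_id`, `table` (data frame),
#'   `n_rows`.
#' @export
load_raw <- function(descriptor) {
  stopifnot(inherits(descriptor, "dataset_descriptor"))
  path <- descriptor$file_path
  if (!file.exists(path))
    mn_io_error(sprintf("dataset '%s': file not found: %s",
                        descriptor$dataset_id, path))
  fmt <- detect_format(path, descriptor$file_format)
  tab <- tryCatch(switch(fmt,
    csv = utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    excel = as.data.frame(readxl::read_excel(path, .name_repair = "minimal"),
                          stringsAsFactors = FALSE),
    sas = if (tolower(tools::file_ext(path)) == "xpt")
      strip_haven_attrs(haven::read_xpt(path)) else
      strip_haven_attrs(haven::read_sas(path)),
    spss = strip_haven_attrs(haven::read_sav(path)),
    stata = strip_haven_attrs(haven::read_dta(path))
  ), error = function(e) {
    if (inherits(e, "mn_error")) stop(e)
    mn_io_error(sprintf("dataset '%s': failed to read '%s' as %s: %s",
                        descriptor$dataset_id, path, fmt, conditionMessage(e)))
  })
  if (is.null(tab) || nrow(tab) == 0L)
    mn_io_error(sprintf("dataset '%s': empty dataset (no data rows in %s)",
                        descriptor$dataset_id, path))
  if (anyDuplicated(names(tab)))
    mn_io_error(sprintf("dataset '%s': duplicated column names in %s",
                        descriptor$dataset_id, path))
  structure(list(dataset_id = descriptor$dataset_id, table = tab,
                 n_rows = nrow(tab)),
            class = "raw_dataset")
}

#' @export
print.raw_dataset <- function(x, ...) {
  cat(sprintf("<raw_dataset> %s: %d rows, %d columns\n",
              x$dataset_id, x$n_rows, ncol(x$table)))
  invisible(x)
}

new_error_report <- function(items) {
  rep <- if (length(items)) do.call(rbind, items) else
    data.frame(severity = character(), dataset_id = character(),
               field = character(), message = character(), stringsAsFactors = FALSE)
  structure(list(items = rep, is_fatal = any(rep$severity == "error")),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  if (nrow(x$items) == 0L) cat("<error_report> no problems detected\n")
  else {
    cat(sprintf("<error_report> %d item(s)%s\n", nrow(x$items),
                if (x$is_fatal) " [FATAL]" else ""))
    print.data.frame(x$items, row.names = FALSE)
  }
  invisible(x)
}

num_coercible <- function(x) {
  if (is.numeric(x)) return(rep(TRUE, length(x)))
  v <- trimws(as.character(x))
  suppressWarnings(ok <- !is.na(as.numeric(v)))
  ok | is.na(x) | v == "" | is.na(v)
}

#' Check a raw dataset against its descriptor before analysis
#'
#' Pure, report-returning pre-analysis audit: existence of every mapped
#' variable, numeric coercibility of age/weight/biomarker columns, strictly
#' positive weights, sex values within the declared coding, group-plausible
#' ages (0-59 months for PSC, 10-60 years for WRA; outside values warn),
#' and two canonical names mapped to the same source column (error).  The
#' pipeline proceeds only when no item has severity `"error"`.
#'
#' @param raw A `raw_dataset` from [load_raw()].
#' @param descriptor Its [dataset_descriptor()].
#' @return An `error_report` (fields `items`, `is_fatal`).
#' @export
check_errors <- function(raw, descriptor) {
  stopifnot(inherits(raw, "raw_dataset"), inherits(descriptor, "dataset_descriptor"))
  tab <- raw$table
  id <- descriptor$dataset_id
  items <- list()
  add <- function(severity, field, msg)
    items[[length(items) + 1L]] <<- data.frame(
      severity = severity, dataset_id = id, field = field, message = msg,
      stringsAsFactors = FALSE)
  mapped <- c(
    stratum = descriptor$survey_design$stratum,
    cluster = descriptor$survey_design$cluster,
    weight = descriptor$survey_design$weight,
    age = descriptor$age_var, sex = descriptor$sex_var)
  if (!is.null(descriptor$biomarkers))
    mapped <- c(mapped, setNames(descriptor$biomarkers$var,
                                 descriptor$biomarkers$biomarker))
  for (f in names(mapped)) {
    if (!mapped[[f]] %in% names(tab))
      add("error", f, sprintf("variable '%s' not found in the dataset", mapped[[f]]))
  }
  dup <- mapped[duplicated(mapped) | duplicated(mapped, fromLast = TRUE)]
  if (length(dup))
    add("error", paste(names(dup), collapse = ","), sprintf(
      "source column(s) %s mapped to more than one canonical variable",
      paste(unique(dup), collapse = ", ")))
  present <- mapped[mapped %in% names(tab)]
  numeric_fields <- setdiff(names(present), c("stratum", "cluster", "sex"))
  for (f in numeric_fields) {
    ok <- num_coercible(tab[[present[[f]]]])
    if (!all(ok))
      add("error", f, sprintf(
        "column '%s' has %d value(s) that are not numeric (first rows: %s)",
        present[[f]], sum(!ok),
        paste(utils::head(which(!ok), 10), collapse = ", ")))
  }
  if (!is.null(descriptor$survey_design$weight) &&
      "weight" %in% names(present) && all(num_coercible(tab[[present[["weight"]]]]))) {
    w <- suppressWarnings(as.numeric(tab[[present[["weight"]]]]))
    if (any(!is.na(w) & w <= 0))
      add("error", "weight", sprintf(
        "weight column '%s' has non-positive value(s) (first rows: %s)",
        present[["weight"]],
        paste(utils::head(which(!is.na(w) & w <= 0), 10), collapse = ", ")))
    if (anyNA(w))
      add("error", "weight", sprintf("weight column '%s' has missing value(s)",
                                     present[["weight"]]))
  }
  if (!is.null(descriptor$sex_var) && "sex" %in% names(present) &&
      !is.null(descriptor$sex_coding)) {
    s <- trimws(as.character(tab[[present[["sex"]]]]))
    ok <- is.na(s) | s == "" | s %in% descriptor$sex_coding
    if (!all(ok))
      add("error", "sex", sprintf(
        "sex column '%s' has value(s) outside the declared coding {%s}: %s",
        present[["sex"]], paste(descriptor$sex_coding, collapse = ", "),
        paste(utils::head(unique(s[!ok]), 5), collapse = ", ")))
  }
  if (!is.null(descriptor$age_var) && "age" %in% names(present) &&
      all(num_coercible(tab[[present[["age"]]]])) &&
      !is.null(descriptor$population_group) &&
      descriptor$population_group %in% c("PSC", "WRA")) {
    a <- suppressWarnings(as.numeric(tab[[present[["age"]]]]))
    months <- if (descriptor$age_unit == "years") a * 12 else a
    lims <- if (descriptor$population_group == "PSC") c(0, 59) else c(120, 720)
    out <- !is.na(months) & (months < lims[1] | months > lims[2])
    if (any(out))
      add("warning", "age", sprintf(
        "%d age value(s) outside the plausible range for %s (first rows: %s)",
        sum(out), descriptor$population_group,
        paste(utils::head(which(out), 10), collapse = ", ")))
  }
  new_error_report(items)
}

#' Standardize a raw dataset to canonical names and codings
#'
#' Renames mapped columns to canonical names (`stratum`, `cluster`,
#' `weight`, `age_months` or `age_years`, `sex`, and the canonical
#' biomarker names), coerces mapped numeric columns, recodes sex to
#' `"male"`/`"female"`, converts PSC ages given in years to months (x 12),
#' and drops unmapped columns from the analytic table.  Row order is
#' preserved.  Values are otherwise untouched (no unit conversion here; see
#' [convert_to_si()]).
#'
#' @param raw A `raw_dataset`.
#' @param descriptor Its [dataset_descriptor()].
#' @param missing_codes Character vector of sentinel strings to treat as
#'   missing in mapped columns (default none).
#' @return A `std_dataset`: list with `dataset_id`, `data` (data frame),
#'   `units` (named source units per biomarker), `flags` (per-row logical
#'   data frame, filled by [recode_zeros()]), `descriptor`, `si_converted`.
#' @export
standardize <- function(raw, descriptor, missing_codes = character()) {
  stopifnot(inherits(raw, "raw_dataset"), inherits(descriptor, "dataset_descriptor"))
  rep <- check_errors(raw, descriptor)
  if (rep$is_fatal)
    mn_validation_error(sprintf(
      "dataset '%s' failed pre-analysis checks:\n%s", descriptor$dataset_id,
      paste(sprintf("- [%s] %s: %s", rep$items$severity, rep$items$field,
                    rep$items$message), collapse = "\n")))
  tab <- raw$table
  n <- nrow(tab)
  as_num <- function(x) {
    x <- as.character(x)
    x[trimws(x) %in% missing_codes] <- NA
    suppressWarnings(as.numeric(x))
  }
  out <- data.frame(row_id = seq_len(n))
  if (!is.null(descriptor$survey_design)) {
    d <- descriptor$survey_design
    if (!is.null(d$stratum)) out$stratum <- as.character(tab[[d$stratum]])
    if (!is.null(d$cluster)) out$cluster <- as.character(tab[[d$cluster]])
    out$weight <- as_num(tab[[d$weight]])
  }
  if (!is.null(descriptor$age_var)) {
    a <- as_num(tab[[descriptor$age_var]])
    grp <- descriptor$population_group %||% "other"
    if (grp == "PSC") {
      out$age_months <- if (descriptor$age_unit == "years") a * 12 else a
    } else {
      out$age_years <- if (descriptor$age_unit == "months") a / 12 else a
    }
  }
  if (!is.null(descriptor$sex_var)) {
    s <- trimws(as.character(tab[[descriptor$sex_var]]))
    s[s %in% missing_codes | s == ""] <- NA
    if (!is.null(descriptor$sex_coding)) {
      sex <- rep(NA_character_, n)
      sex[!is.na(s) & s == descriptor$sex_coding[["male"]]] <- "male"
      sex[!is.na(s) & s == descriptor$sex_coding[["female"]]] <- "female"
      out$sex <- sex
    } else {
      s0 <- tolower(s)
      sex <- rep(NA_character_, n)
      sex[s0 %in% c("male", "m")] <- "male"
      sex[s0 %in% c("female", "f")] <- "female"
      out$sex <- sex
    }
  }
  units <- character(0)
  if (!is.null(descriptor$biomarkers)) {
    for (i in seq_len(nrow(descriptor$biomarkers))) {
      bm <- descriptor$biomarkers$biomarker[i]
      out[[bm]] <- as_num(tab[[descriptor$biomarkers$var[i]]])
      units[bm] <- descriptor$biomarkers$unit[i]
    }
  }
  flags <- data.frame(row_id = out$row_id)
  structure(list(dataset_id = descriptor$dataset_id, data = out,
                 units = units, flags = flags, descriptor = descriptor,
                 si_converted = FALSE),
            class = "std_dataset")
}

#' @export
print.std_dataset <- function(x, ...) {
  cat(sprintf("<std_dataset> %s: %d rows; biomarkers: %s%s\n", x$dataset_id,
              nrow(x$data), paste(names(x$units), collapse = ", "),
              if (isTRUE(x$si_converted)) " [SI]" else ""))
  invisible(x)
}

#' Build a standardized dataset from an in-memory data frame
#'
#' For data already cleaned in R: wraps a data frame whose columns use the
#' canonical names (`stratum`, `cluster`, `weight`, `age_months` or
#' `age_years`, `sex` coded `"male"`/`"female"`, and canonical biomarker
#' names) into a `std_dataset`, skipping file ingestion.  By default the
#' values are declared to be in canonical SI units already.
#'
#' @param data The data frame.
#' @param biomarkers Canonical biomarker column names present in `data`.
#' @param group Population group (`"PSC"`, `"WRA"`, `"other"`).
#' @param dataset_id Label for the dataset.
#' @param units Named source units per biomarker; default canonical SI.
#' @param recode Apply the zero recode (default `TRUE`).
#' @return A `std_dataset` (SI-converted if `units` are canonical).
#' @export
as_std_dataset <- function(data, biomarkers, group = "other",
                           dataset_id = "data",
                           units = canonical_units()[biomarkers],
                           recode = TRUE) {
  miss <- setdiff(biomarkers, names(data))
  if (length(miss))
    mn_validation_error(sprintf("column(s) not in data: %s",
                                paste(miss, collapse = ", ")))
  units <- setNames(as.character(units), biomarkers)
  desc <- dataset_descriptor(
    dataset_id = dataset_id, file_path = "<in-memory>",
    population_group = if (identical(group, "other")) "other" else group,
    biomarkers = data.frame(biomarker = biomarkers, var = biomarkers,
                            unit = unname(units), stringsAsFactors = FALSE))
  keep <- intersect(c("row_id", "stratum", "cluster", "weight", "age_months",
                      "age_years", "sex", biomarkers), names(data))
  d <- as.data.frame(data)[, keep, drop = FALSE]
  if (!"row_id" %in% names(d)) d <- cbind(row_id = seq_len(nrow(d)), d)
  ds <- structure(list(dataset_id = dataset_id, data = d, units = units,
                       flags = data.frame(row_id = d$row_id),
                       descriptor = desc, si_converted = FALSE),
                  class = "std_dataset")
  if (recode) ds <- recode_zeros(ds)
  canon <- canonical_units()
  si_already <- all(vapply(biomarkers, function(b)
    !b %in% names(canon) || norm_unit(units[[b]]) == norm_unit(canon[[b]]),
    logical(1)))
  if (si_already) ds$si_converted <- TRUE else ds <- convert_to_si(ds)
  ds
}

#' Recode exact zeros to 0.0001 for log transformation
#'
#' Every biomarker value of exactly 0 becomes 0.0001 (in the column's
#' current unit, i.e. before SI conversion) and the row is flagged
#' `zero_recoded_<biomarker>`.  Negative values are never recoded: they
#' violate the concentration invariant and are reported by
#' [check_errors()]/[standardize()] upstream.  Idempotent.
#'
#' @param ds A `std_dataset`.
#' @return The dataset with zeros recoded and flags set.
#' @export
recode_zeros <- function(ds) {
  stopifnot(inherits(ds, "std_dataset"))
  for (bm in names(ds$units)) {
    z <- !is.na(ds$data[[bm]]) & ds$data[[bm]] == 0
    flag_col <- paste0("zero_recoded_", bm)
    prev <- ds$flags[[flag_col]] %||% rep(FALSE, nrow(ds$data))
    ds$data[[bm]][z] <- 1e-4
    ds$flags[[flag_col]] <- prev | z
  }
  ds
}
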