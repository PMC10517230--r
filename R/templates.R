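# Dataset-descriptor and cutoff templates: the two user-facing
# configuration artifacts driving a run.
#
# Dataset template layout: rows are fields, one column per dataset, the
# first column holding the field labels.  Canonical field rows are
#   file, format, stratum, cluster, weight, age, age_unit,
#   sex, sex_male, sex_female, population_group
# plus one `<biomarker>_var` / `<biomarker>_unit` row pair per biomarker
# (arbitrary biomarker names allowed).  Label matching is case-insensitive
# with surrounding whitespace stripped; empty cells mean "absent".

mn_fixed_fields <- function() {
  c("file", "format", "stratum", "cluster", "weight",
    "age", "age_unit", "sex", "sex_male", "sex_female", "population_group")
}

norm_label <- function(x) tolower(trimws(as.character(x)))

norm_age_unit <- function(u, context = "age_unit") {
  u0 <- norm_label(u)
  if (u0 %in% c("months", "month", "mo", "m")) return("months")
  if (u0 %in% c("years", "year", "yr", "y")) return("years")
  mn_validation_error(sprintf("%s must be months or years (got '%s')", context, u))
}

norm_group <- function(g) {
  g0 <- norm_label(g)
  if (g0 == "psc") return("PSC")
  if (g0 == "wra") return("WRA")
  if (g0 %in% c("other", "any")) return(g0)
  mn_validation_error(sprintf("unknown population group '%s'", g))
}

# Read a rows-are-fields template sheet as a character matrix.
read_template_table <- function(path) {
  if (!file.exists(path)) mn_io_error(sprintf("template file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    tab <- readxl::read_excel(path, col_types = "text", .name_repair = "minimal")
    tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  }
  if (ncol(tab) < 2L)
    mn_validation_error(sprintf("template '%s' has no dataset columns", path))
  tab
}

#' Construct a dataset descriptor
#'
#' Programmatic equivalent of one column of the dataset template.
#'
#' @param dataset_id Short unique label for the dataset.
#' @param file_path Path to the participant-level data file.
#' @param file_format One of `"csv"`, `"excel"`, `"sas"`, `"spss"`,
#'   `"stata"`, or `"auto"` (detect from the file extension).
#' @param survey_design Optional named list with elements `stratum`,
#'   `cluster`, `weight` giving source column names (any subset, but
#'   `weight` is required when any element is given).
#' @param age_var,age_unit Source column holding age and its unit
#'   (`"months"` or `"years"`).
#' @param sex_var Source column holding sex.
#' @param sex_coding Named character vector `c(male = , female = )` giving
#'   the source codes of the two levels.
#' @param population_group `"PSC"`, `"WRA"` or `"other"`.
#' @param biomarkers Data frame with columns `biomarker` (canonical name),
#'   `var` (source column), `unit` (source unit); include rows for `agp`
#'   and `crp` when present.
#' @param registry Conversion registry used to validate declared units.
#' @return A `dataset_descriptor` object.
#' @export
dataset_descriptor <- function(dataset_id, file_path, file_format = "auto",
                               survey_design = NULL,
                               age_var = NULL, age_unit = NULL,
                               sex_var = NULL, sex_coding = NULL,
                               population_group = NULL,
                               biomarkers = NULL,
                               registry = si_registry()) {
  if (!is_scalar_chr(dataset_id) || !nzchar(trimws(dataset_id)))
    mn_validation_error("dataset_id must be a non-empty string")
  if (!is_scalar_chr(file_path) || !nzchar(file_path))
    mn_validation_error(sprintf("dataset '%s': file path is required", dataset_id))
  file_format <- norm_label(file_format %||% "auto")
  ok_fmt <- c("csv", "excel", "sas", "spss", "stata", "auto")
  if (!file_format %in% ok_fmt)
    mn_validation_error(sprintf("dataset '%s': unknown format '%s'",
                                dataset_id, file_format))
  if (!is.null(survey_design)) {
    survey_design <- survey_design[!vapply(survey_design, is.null, logical(1))]
    if (length(survey_design) == 0L) survey_design <- NULL
  }
  if (!is.null(survey_design)) {
    bad <- setdiff(names(survey_design), c("stratum", "cluster", "weight"))
    if (length(bad))
      mn_validation_error(sprintf("dataset '%s': unknown design element(s) %s",
                                  dataset_id, paste(bad, collapse = ", ")))
    if (is.null(survey_design$weight))
      mn_validation_error(sprintf(
        "dataset '%s': survey design declared without a weight variable", dataset_id))
  }
  if (!is.null(age_unit)) age_unit <- norm_age_unit(age_unit,
    sprintf("dataset '%s': age_unit", dataset_id))
  if (!is.null(age_var) && is.null(age_unit))
    mn_validation_error(sprintf("dataset '%s': age variable declared without age_unit",
                                dataset_id))
  if (!is.null(sex_coding)) {
    if (!all(c("male", "female") %in% names(sex_coding)))
      mn_validation_error(sprintf(
        "dataset '%s': sex_coding must name both male and female codes", dataset_id))
    sex_coding <- c(male = trimws(as.character(sex_coding[["male"]])),
                    female = trimws(as.character(sex_coding[["female"]])))
  }
  if (!is.null(population_group)) {
    population_group <- norm_group(population_group)
    if (population_group == "any")
      mn_validation_error(sprintf(
        "dataset '%s': population_group must be PSC, WRA or other", dataset_id))
  }
  if (!is.null(biomarkers)) {
    if (!all(c("biomarker", "var", "unit") %in% names(biomarkers)))
      mn_validation_error("biomarkers must have columns biomarker, var, unit")
    biomarkers <- data.frame(biomarker = as.character(biomarkers$biomarker),
                             var = as.character(biomarkers$var),
                             unit = as.character(biomarkers$unit),
                             stringsAsFactors = FALSE)
    dup <- biomarkers$biomarker[duplicated(biomarkers$biomarker)]
    if (length(dup))
      mn_validation_error(sprintf(
        "dataset '%s': biomarker(s) mapped more than once: %s",
        dataset_id, paste(unique(dup), collapse = ", ")))
    for (i in seq_len(nrow(biomarkers))) {
      bm <- biomarkers$biomarker[i]
      if (is.null(lookup_conversion(registry, bm, biomarkers$unit[i])))
        mn_validation_error(sprintf(
          "dataset '%s': unit '%s' is not registered for biomarker '%s'",
          dataset_id, biomarkers$unit[i], bm))
    }
    if (nrow(biomarkers) == 0L) biomarkers <- NULL
  }
  structure(list(
    dataset_id = trimws(dataset_id), file_path = file_path,
    file_format = file_format, survey_design = survey_design,
    age_var = age_var, age_unit = age_unit,
    sex_var = sex_var, sex_coding = sex_coding,
    population_group = population_group, biomarkers = biomarkers
  ), class = "dataset_descriptor")
}

#' @export
print.dataset_descriptor <- function(x, ...) {
  cat(sprintf("<dataset_descriptor> %s\n  file: %s (%s)\n", x$dataset_id,
              x$file_path, x$file_format))
  if (!is.null(x$survey_design))
    cat("  design:", paste(names(x$survey_design), unlist(x$survey_design),
                           sep = "=", collapse = ", "), "\n")
  if (!is.null(x$population_group)) cat("  group:", x$population_group, "\n")
  if (!is.null(x$biomarkers))
    cat("  biomarkers:", paste(x$biomarkers$biomarker, collapse = ", "), "\n")
  invisible(x)
}

#' Load the dataset-descriptor template
#'
#' Reads a rows-are-fields template (CSV or Excel, recognised by extension)
#' and returns one validated [dataset_descriptor()] per non-empty dataset
#' column, in column order.  Relative `file` entries are resolved against
#' the template's own directory.
#'
#' @param path Template file.
#' @param registry Conversion registry used to validate declared units.
#' @return List of `dataset_descriptor` objects.
#' @export
load_dataset_template <- function(path, registry = si_registry()) {
  tab <- read_template_table(path)
  labels <- norm_label(tab[[1L]])
  fixed <- mn_fixed_fields()
  is_bm_var <- grepl("_var$", labels)
  is_bm_unit <- grepl("_unit$", labels) & !labels %in% "age_unit"
  unknown <- !(labels %in% fixed | is_bm_var | is_bm_unit)
  if (any(unknown))
    mn_validation_error(sprintf("unknown template field row(s): %s",
                                paste(tab[[1L]][unknown], collapse = ", ")))
  dup <- labels[duplicated(labels)]
  if (length(dup))
    mn_validation_error(sprintf("duplicated template field row(s): %s",
                                paste(unique(dup), collapse = ", ")))
  ids <- trimws(names(tab)[-1L])
  cols <- which(vapply(seq_along(ids), function(j) {
    any(nzchar(trimws(tab[[j + 1L]])), na.rm = TRUE)
  }, logical(1)))
  ids <- ids[cols]
  if (anyDuplicated(ids)) {
    d <- ids[duplicated(ids)][1L]
    mn_validation_error(sprintf(
      "duplicated dataset_id '%s' (columns %s)", d,
      paste(which(ids == d), collapse = " and ")))
  }
  base_dir <- dirname(normalizePath(path))
  get <- function(col, label) {
    i <- match(label, labels)
    if (is.na(i)) return(NULL)
    v <- trimws(col[i])
    if (is.na(v) || !nzchar(v)) NULL else v
  }
  out <- vector("list", length(cols))
  for (k in seq_along(cols)) {
    col <- tab[[cols[k] + 1L]]
    fp <- get(col, "file")
    if (is.null(fp))
      mn_validation_error(sprintf("dataset '%s': file row is empty", ids[k]))
    if (!grepl("^(/|[A-Za-z]:)", fp)) fp <- file.path(base_dir, fp)
    design <- list(stratum = get(col, "stratum"), cluster = get(col, "cluster"),
                   weight = get(col, "weight"))
    design <- design[!vapply(design, is.null, logical(1))]
    if (length(design) == 0L) design <- NULL
    sm <- get(col, "sex_male"); sf <- get(col, "sex_female")
    coding <- if (!is.null(sm) || !is.null(sf))
      c(male = sm %||% NA_character_, female = sf %||% NA_character_) else NULL
    bm_names <- sub("_var$", "", labels[is_bm_var])
    bm <- do.call(rbind, lapply(bm_names, function(b) {
      v <- get(col, paste0(b, "_var"))
      if (is.null(v)) return(NULL)
      u <- get(col, paste0(b, "_unit"))
      if (is.null(u))
        mn_validation_error(sprintf(
          "dataset '%s': biomarker '%s' has a variable but no unit", ids[k], b))
      data.frame(biomarker = b, var = v, unit = u, stringsAsFactors = FALSE)
    }))
    out[[k]] <- dataset_descriptor(
      dataset_id = ids[k], file_path = fp,
      file_format = get(col, "format") %||% "auto",
      survey_design = design,
      age_var = get(col, "age"), age_unit = get(col, "age_unit"),
      sex_var = get(col, "sex"), sex_coding = coding,
      population_group = get(col, "population_group"),
      biomarkers = bm, registry = registry)
  }
  out
}

#' Write dataset descriptors back to template layout
#'
#' Inverse of [load_dataset_template()]: the written file re-loads to an
#' equal descriptor list.
#'
#' @param descriptors List of `dataset_descriptor` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_template <- function(descriptors, path) {
  if (inherits(descriptors, "dataset_descriptor")) descriptors <- list(descriptors)
  bm_names <- unique(unlist(lapply(descriptors, function(d)
    if (is.null(d$biomarkers)) character() else d$biomarkers$biomarker)))
  fields <- c(mn_fixed_fields(),
              as.vector(rbind(paste0(bm_names, "_var"), paste0(bm_names, "_unit"))))
  out <- data.frame(field = fields, stringsAsFactors = FALSE)
  for (d in descriptors) {
    col <- setNames(rep("", length(fields)), fields)
    col["file"] <- d$file_path
    col["format"] <- if (d$file_format == "auto") "" else d$file_format
    if (!is.null(d$survey_design)) {
      for (el in names(d$survey_design)) col[el] <- d$survey_design[[el]]
    }
    col["age"] <- d$age_var %||% ""
    col["age_unit"] <- d$age_unit %||% ""
    col["sex"] <- d$sex_var %||% ""
    if (!is.null(d$sex_coding)) {
      col["sex_male"] <- d$sex_coding[["male"]]
      col["sex_female"] <- d$sex_coding[["female"]]
    }
    col["population_group"] <- d$population_group %||% ""
    if (!is.null(d$biomarkers)) {
      for (i in seq_len(nrow(d$biomarkers))) {
        b <- d$biomarkers$biomarker[i]
        col[paste0(b, "_var")] <- d$biomarkers$var[i]
        col[paste0(b, "_unit")] <- d$biomarkers$unit[i]
      }
    }
    out[[d$dataset_id]] <- unname(col)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Cutoff template

#' Load a biomarker cutoff template
#'
#' One row per rule; columns `biomarker, condition_label, group, sex,
#' age_min, age_max, age_unit, direction, threshold, threshold_unit,
#' use_adjusted, source`.  Thresholds are converted to the biomarker's SI
#' unit at load time.  Rules for the same `(biomarker, condition_label)`
#' must not overlap in (group x sex x age) coverage, so a participant can
#' never match two rules for one condition.
#'
#' @param path CSV or Excel file; defaults to the packaged cutoff table
#'   (WHO/IZiNCG defaults, including serum ferritin < 12 ug/L for
#'   preschool-aged children and < 15 ug/L for women of reproductive age,
#'   and serum retinol < 0.7 umol/L for vitamin A deficiency).
#' @param registry Conversion registry used to convert thresholds to SI.
#' @return A `cutoff_table` object (a data frame of validated rules).
#' @export
load_cutoff_template <- function(path = default_cutoff_path(),
                                 registry = si_registry()) {
  if (!file.exists(path)) mn_io_error(sprintf("cutoff template not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext %in% c("xlsx", "xls")) {
    as.data.frame(readxl::read_excel(path, col_types = "text"),
                  stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, colClasses = "character", check.names = TRUE)
  }
  need <- c("biomarker", "condition_label", "group", "sex", "age_min", "age_max",
            "age_unit", "direction", "threshold", "threshold_unit", "use_adjusted")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    mn_validation_error(sprintf("cutoff template missing column(s): %s",
                                paste(miss, collapse = ", ")))
  if (!"source" %in% names(tab)) tab$source <- ""
  n <- nrow(tab)
  rules <- data.frame(
    biomarker = trimws(tab$biomarker),
    condition_label = trimws(tab$condition_label),
    group = vapply(tab$group, norm_group, character(1), USE.NAMES = FALSE),
    sex = norm_label(tab$sex),
    age_min = as.numeric(tab$age_min), age_max = as.numeric(tab$age_max),
    age_unit = vapply(tab$age_unit, norm_age_unit, character(1), USE.NAMES = FALSE),
    direction = norm_label(tab$direction),
    threshold = as.numeric(tab$threshold),
    threshold_unit = trimws(tab$threshold_unit),
    use_adjusted = norm_label(tab$use_adjusted) %in% c("true", "t", "1", "yes"),
    source = tab$source,
    stringsAsFactors = FALSE)
  if (n > 0L) {
    bad_sex <- !rules$sex %in% c("male", "female", "any")
    if (any(bad_sex))
      mn_validation_error(sprintf("cutoff row(s) %s: sex must be male, female or any",
                                  paste(which(bad_sex), collapse = ", ")))
    if (any(rules$group == "other"))
      mn_validation_error("cutoff rules must use group PSC, WRA or any")
    bad_dir <- !rules$direction %in% c("below", "above")
    if (any(bad_dir))
      mn_validation_error(sprintf("cutoff row(s) %s: direction must be below or above",
                                  paste(which(bad_dir), collapse = ", ")))
    bad_thr <- !is.finite(rules$threshold) | rules$threshold <= 0
    if (any(bad_thr))
      mn_validation_error(sprintf("cutoff row(s) %s: threshold must be > 0",
                                  paste(which(bad_thr), collapse = ", ")))
    bad_age <- !is.finite(rules$age_min) | !is.finite(rules$age_max) |
      rules$age_min >= rules$age_max
    if (any(bad_age))
      mn_validation_error(sprintf("cutoff row(s) %s: need age_min < age_max",
                                  paste(which(bad_age), collapse = ", ")))
    # convert thresholds to SI
    for (i in seq_len(n)) {
      hit <- lookup_conversion(registry, rules$biomarker[i], rules$threshold_unit[i])
      if (is.null(hit))
        mn_validation_error(sprintf(
          "cutoff row %d: unit '%s' is not registered for biomarker '%s'",
          i, rules$threshold_unit[i], rules$biomarker[i]))
      rules$threshold[i] <- rules$threshold[i] * hit$factor
      rules$threshold_unit[i] <- hit$to_unit
    }
    check_rule_overlaps(rules)
  }
  structure(rules, class = c("cutoff_table", "data.frame"))
}

# age interval in months, closed on both ends
rule_age_months <- function(rules) {
  f <- ifelse(rules$age_unit == "years", 12, 1)
  cbind(lo = rules$age_min * f, hi = rules$age_max * f)
}

check_rule_overlaps <- function(rules) {
  key <- paste(rules$biomarker, rules$condition_label, sep = "\r")
  age <- rule_age_months(rules)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    for (a in seq_along(idx)[-length(idx)]) for (b in seq.int(a + 1L, length(idx))) {
      i <- idx[a]; j <- idx[b]
      grp <- rules$group[i] == rules$group[j] ||
        rules$group[i] == "any" || rules$group[j] == "any"
      sx <- rules$sex[i] == rules$sex[j] ||
        rules$sex[i] == "any" || rules$sex[j] == "any"
      ag <- age[i, "lo"] <= age[j, "hi"] && age[j, "lo"] <= age[i, "hi"]
      if (grp && sx && ag)
        mn_validation_error(sprintf(
          "overlapping cutoff rules for %s/%s: rows %d and %d cover the same group/sex/age",
          rules$biomarker[i], rules$condition_label[i], i, j))
    }
  }
  invisible(TRUE)
}

#' Path of the packaged default cutoff table
#' @return Filesystem path to the shipped CSV.
#' @export
default_cutoff_path <- function() {
  system.file("extdata", "cutoff_template_default.csv", package = "mnsurvey",
              mustWork = TRUE)
}

#' Look up the cutoff rule matching a participant
#'
#' @param cutoffs A `cutoff_table`.
#' @param biomarker Canonical biomarker name.
#' @param group Participant's population group (`"PSC"`, `"WRA"`, `"other"`).
#' @param age Age value.
#' @param age_unit `"months"` or `"years"`.
#' @param sex `"male"`, `"female"` or `NA`.
#' @param condition_label Optional condition to restrict to.
#' @return The matching rule rows (0 or 1 per condition) as a data frame.
#' @export
lookup_cutoff <- function(cutoffs, biomarker, group, age, age_unit,
                          sex = NA_character_, condition_label = NULL) {
  stopifnot(inherits(cutoffs, "cutoff_table"))
  if (nrow(cutoffs) == 0L) return(cutoffs)
  age_m <- if (norm_age_unit(age_unit) == "years") age * 12 else age
  ra <- rule_age_months(cutoffs)
  grp_ok <- cutoffs$group == "any" | cutoffs$group == group
  sex_ok <- cutoffs$sex == "any" | (!is.na(sex) & cutoffs$sex == sex)
  age_ok <- ra[, "lo"] <= age_m & age_m <= ra[, "hi"]
  hit <- cutoffs$biomarker == biomarker & grp_ok & sex_ok & age_ok
  if (!is.null(condition_label)) hit <- hit & cutoffs$condition_label == condition_label
  cutoffs[hit, , drop = FALSE]
}

#' Cross-validate dataset descriptors against a cutoff table
#'
#' Report-returning consistency check: flags cutoff rules whose biomarker
#' is not mapped in any descriptor, and descriptors to which no rule can
#' apply.  Never errors and never mutates its inputs.
#'
#' @param descriptors List of `dataset_descriptor`s.
#' @param cutoffs A `cutoff_table`.
#' @return A `validation_report` data frame with columns
#'   `severity, dataset_id, field, message` (zero rows when fully matching).
#' @export
validate_templates <- function(descriptors, cutoffs) {
  if (inherits(descriptors, "dataset_descriptor")) descriptors <- list(descriptors)
  items <- list()
  add <- function(severity, id, field, msg)
    items[[length(items) + 1L]] <<- data.frame(
      severity = severity, dataset_id = id, field = field, message = msg,
      stringsAsFactors = FALSE)
  mapped <- unique(unlist(lapply(descriptors, function(d)
    if (is.null(d$biomarkers)) character() else d$biomarkers$biomarker)))
  unused <- setdiff(unique(cutoffs$biomarker), mapped)
  for (b in unused)
    add("warning", "", b, sprintf(
      "cutoff rules for '%s' are unused: not mapped in any dataset", b))
  for (d in descriptors) {
    if (is.null(d$biomarkers)) {
      add("warning", d$dataset_id, "", "no biomarkers mapped")
      next
    }
    grp <- d$population_group %||% "other"
    applicable <- cutoffs$biomarker %in% d$biomarkers$biomarker &
      (cutoffs$group == "any" | cutoffs$group == grp)
    if (nrow(cutoffs) > 0L && !any(applicable))
      add("warning", d$dataset_id, "population_group", sprintf(
        "no cutoff rule applies to group '%s' for the mapped biomarkers", grp))
    if (is.null(d$age_var) && nrow(cutoffs) > 0L)
      add("warning", d$dataset_id, "age",
          "no age variable mapped: age-specific cutoffs cannot be matched")
  }
  rep <- if (length(items)) do.call(rbind, items) else
    data.frame(severity = character(), dataset_id = character(),
               field = character(), message = character(), stringsAsFactors = FALSE)
  structure(rep, class = c("validation_report", "data.frame"))
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) cat("<validation_report> no findings\n")
  else {
    cat(sprintf("<validation_report> %d finding(s)\n", nrow(x)))
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.cutoff_table <- function(x, ...) {
  cat(sprintf("<cutoff_table> %d rule(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(x[, setdiff(names(x), "source")], row.names = FALSE)
  invisible(x)
}
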