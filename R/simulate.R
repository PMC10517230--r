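# Synthetic stratified-cluster survey fixtures with known truth.
#
# Observed log-concentrations are linear in the log inflammation markers:
#   ln X = mu + delta_h + u_psu + b1 ln AGP + b2 ln CRP + eps
# with delta_h a fixed stratum shift, u_psu a cluster random intercept and
# eps ~ N(0, sigma^2).  The truth sidecar stores, per row, the
# concentration with the above-baseline inflammation effect removed,
#   X_free = exp(ln X - b1 max(ln AGP - r_a, 0) - b2 max(ln CRP - r_c, 0)),
# where r_a, r_c are the population 10th percentiles of the ln markers —
# the same lowest-decile reference concept the regression correction uses,
# so X_free is the estimand the adjustment targets.  Deficiency truth is
# X_free below the condition cutoff (strict).
#
# Weights are a deterministic function of stratum only, which keeps the
# design-based estimators unbiased and the analytic truth computable.

#' Specify a synthetic survey
#'
#' Defaults describe a moderate-size stratified cluster survey of
#' preschool-aged children with ferritin (inflammation-elevated, ln-slope
#' 0.8 on ln AGP) and retinol (inflammation-depressed, ln-slope -0.4),
#' AGP around 0.8 g/L and CRP around 1 mg/L on the log scale, a between-PSU
#' log-scale SD of 0.2 (log-scale ICC about 8% for ferritin) and
#' stratum-informative weights in [1, 3].
#'
#' @param n_strata,psus_per_stratum,rows_per_psu Design dimensions.
#' @param group `"PSC"` or `"WRA"`.
#' @param biomarker_params Named list; per biomarker a list with `mu`
#'   (ln-scale mean), `sigma` (ln-scale residual SD), `b1` (slope on ln
#'   AGP), `b2` (slope on ln CRP).
#' @param inflammation_params List with `ln_agp_mean`, `ln_agp_sd`,
#'   `ln_crp_mean`, `ln_crp_sd` (SI units g/L and mg/L).
#' @param cluster_sd Between-PSU SD of the ln-scale random intercept.
#' @param stratum_shift Amplitude `a` of fixed ln-scale stratum shifts
#'   (equally spaced on `[-a, a]`).
#' @param weight_range Range of the stratum-level sampling-weight
#'   multiplier.
#' @param truth_cutoffs Named numeric vector of SI thresholds defining true
#'   deficiency (`X_free` strictly below); defaults follow the group
#'   (ferritin 12 ug/L for PSC, 15 ug/L for WRA; retinol 0.7 umol/L).
#' @param seed Integer seed; identical spec + seed gives identical files.
#' @return A `sim_spec` object.
#' @export
sim_spec <- function(n_strata = 4L, psus_per_stratum = 8L, rows_per_psu = 15L,
                     group = c("PSC", "WRA"),
                     biomarker_params = NULL,
                     inflammation_params = list(
                       ln_agp_mean = log(0.8), ln_agp_sd = 0.4,
                       ln_crp_mean = log(1.0), ln_crp_sd = 1.0),
                     cluster_sd = 0.2,
                     stratum_shift = 0.15,
                     weight_range = c(1, 3),
                     truth_cutoffs = NULL,
                     seed = 1L) {
  group <- match.arg(group)
  if (is.null(biomarker_params))
    biomarker_params <- list(
      ferritin = list(mu = log(30), sigma = 0.7, b1 = 0.8, b2 = 0.25),
      retinol = list(mu = log(1.05), sigma = 0.25, b1 = -0.4, b2 = -0.15))
  if (is.null(truth_cutoffs)) {
    truth_cutoffs <- c(ferritin = if (group == "PSC") 12 else 15, retinol = 0.7)
    truth_cutoffs <- truth_cutoffs[names(truth_cutoffs) %in% names(biomarker_params)]
  }
  stopifnot(n_strata >= 1L, psus_per_stratum >= 1L, rows_per_psu >= 1L,
            cluster_sd >= 0, length(weight_range) == 2L,
            all(weight_range > 0))
  for (p in biomarker_params) stopifnot(p$sigma > 0)
  stopifnot(inflammation_params$ln_agp_sd > 0, inflammation_params$ln_crp_sd > 0)
  structure(list(n_strata = as.integer(n_strata),
                 psus_per_stratum = as.integer(psus_per_stratum),
                 rows_per_psu = as.integer(rows_per_psu),
                 group = group, biomarker_params = biomarker_params,
                 inflammation_params = inflammation_params,
                 cluster_sd = cluster_sd, stratum_shift = stratum_shift,
                 weight_range = weight_range, truth_cutoffs = truth_cutoffs,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf("<sim_spec> %s: %d strata x %d PSUs x %d rows (n = %d), seed %d\n",
              x$group, x$n_strata, x$psus_per_stratum, x$rows_per_psu,
              x$n_strata * x$psus_per_stratum * x$rows_per_psu, x$seed))
  invisible(x)
}

# population 10th percentile of a ln marker
sim_baseline <- function(m, s) m + stats::qnorm(0.10) * s

#' Simulate a survey in memory
#'
#' Draws the participant table on the analysis scale (canonical names, SI
#' units) together with the truth sidecar, without touching the disk.
#' [generate_survey_dataset()] is a thin wrapper that renames columns to
#' raw-file conventions, de-converts units and serializes.
#'
#' @param spec A [sim_spec()].
#' @return List with `data` (columns `row_id`, `stratum`, `psu`, `weight`,
#'   `age`, `sex`, `agp`, `crp`, biomarkers), `truth` (per-row
#'   `<biomarker>_free` and `true_def_<biomarker>` columns) and `baselines`
#'   (the ln-scale population reference values used for the truth).
#' @export
simulate_survey <- function(spec) {
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  H <- spec$n_strata; J <- spec$psus_per_stratum; m <- spec$rows_per_psu
  n <- H * J * m
  stratum <- rep(seq_len(H), each = J * m)
  psu <- rep(seq_len(H * J), each = m)
  delta <- if (H > 1)
    seq(-spec$stratum_shift, spec$stratum_shift, length.out = H) else 0
  wts <- if (H > 1)
    seq(spec$weight_range[1], spec$weight_range[2], length.out = H)
  else mean(spec$weight_range)
  u <- stats::rnorm(H * J, 0, spec$cluster_sd)
  ip <- spec$inflammation_params
  ln_agp <- stats::rnorm(n, ip$ln_agp_mean, ip$ln_agp_sd)
  ln_crp <- stats::rnorm(n, ip$ln_crp_mean, ip$ln_crp_sd)
  r_a <- sim_baseline(ip$ln_agp_mean, ip$ln_agp_sd)
  r_c <- sim_baseline(ip$ln_crp_mean, ip$ln_crp_sd)
  out <- data.frame(
    row_id = seq_len(n), stratum = stratum, psu = psu,
    weight = wts[stratum],
    age = if (spec$group == "PSC") round(stats::runif(n, 6, 59), 1)
      else round(stats::runif(n, 15, 49), 1),
    sex = if (spec$group == "PSC") sample(1:2, n, replace = TRUE)
      else rep(2L, n),
    agp = exp(ln_agp), crp = exp(ln_crp))
  truth <- data.frame(row_id = out$row_id)
  for (bm in names(spec$biomarker_params)) {
    p <- spec$biomarker_params[[bm]]
    eps <- stats::rnorm(n, 0, p$sigma)
    ln_x <- p$mu + delta[stratum] + u[psu] + p$b1 * ln_agp + p$b2 * ln_crp + eps
    ln_free <- ln_x - p$b1 * pmax(ln_agp - r_a, 0) - p$b2 * pmax(ln_crp - r_c, 0)
    out[[bm]] <- exp(ln_x)
    truth[[paste0(bm, "_free")]] <- exp(ln_free)
    if (bm %in% names(spec$truth_cutoffs))
      truth[[paste0("true_def_", bm)]] <-
        as.numeric(exp(ln_free) < spec$truth_cutoffs[[bm]])
  }
  list(data = out, truth = truth, baselines = c(ln_agp_ref = r_a, ln_crp_ref = r_c))
}

sim_raw_columns <- function(spec) {
  # raw-file column names and source units, chosen to exercise name
  # standardization and unit conversion (retinol shipped in ug/dL)
  bm <- names(spec$biomarker_params)
  vars <- c(ferritin = "FER", retinol = "retinol_ugdl")[bm]
  vars[is.na(vars)] <- bm[is.na(vars)]
  units <- setNames(canonical_units()[bm], bm)
  if ("retinol" %in% bm) units[["retinol"]] <- "ug/dL"
  list(vars = vars, units = units)
}

#' Generate a synthetic survey dataset on disk
#'
#' Writes the participant file in the requested format(s) plus a
#' `<name>_truth.csv` sidecar holding the inflammation-free concentrations
#' and true deficiency status per row.  Raw column names deliberately
#' differ from the canonical ones (e.g. ferritin is stored as `FER`) and
#' retinol is stored in ug/dL, so a full pipeline run must standardize and
#' convert.
#'
#' @param spec A [sim_spec()].
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("csv", "excel", "sas", "spss", "stata")`.
#' @param name Base name for the files.
#' @return Invisibly, a list with `paths` (named by format), `truth_path`,
#'   `data` (raw table as written), `truth`, `baselines` (the ln-scale
#'   population reference values used for the truth), and `spec`.
#' @export
generate_survey_dataset <- function(spec, dir, formats = "csv", name = "survey") {
  stopifnot(inherits(spec, "sim_spec"))
  formats <- match.arg(formats, c("csv", "excel", "sas", "spss", "stata"),
                       several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_survey(spec)
  cols <- sim_raw_columns(spec)
  raw <- data.frame(
    strat = sim$data$stratum, psu = sim$data$psu, wt = sim$data$weight,
    sex = sim$data$sex, agp = sim$data$agp, crp = sim$data$crp)
  raw[[if (spec$group == "PSC") "age_mo" else "age_y"]] <- sim$data$age
  for (bm in names(spec$biomarker_params)) {
    hit <- lookup_conversion(si_registry(), bm, cols$units[[bm]])
    raw[[cols$vars[[bm]]]] <- sim$data[[bm]] / hit$factor  # back to source unit
  }
  paths <- character(0)
  for (fmt in formats) {
    p <- file.path(dir, paste0(name, ".", switch(fmt,
      csv = "csv", excel = "xlsx", sas = "xpt", spss = "sav", stata = "dta")))
    switch(fmt,
      csv = utils::write.csv(raw, p, row.names = FALSE, quote = FALSE),
      excel = write_minimal_xlsx(raw, p),
      sas = haven::write_xpt(raw, p),
      spss = haven::write_sav(raw, p),
      stata = haven::write_dta(raw, p))
    paths[fmt] <- p
  }
  truth_path <- file.path(dir, paste0(name, "_truth.csv"))
  utils::write.csv(sim$truth, truth_path, row.names = FALSE, quote = FALSE)
  invisible(list(paths = paths, truth_path = truth_path, data = raw,
                 truth = sim$truth, baselines = sim$baselines, spec = spec))
}

#' Generate descriptor and cutoff templates matching a synthetic dataset
#'
#' Emits a one-column dataset template and a cutoff table consistent with
#' the variable names and units written by [generate_survey_dataset()];
#' the pair loads through [load_dataset_template()] /
#' [load_cutoff_template()] unchanged.
#'
#' @param spec The [sim_spec()] used to generate the data.
#' @param data_path Path of the generated participant file.
#' @param dir Output directory for the templates.
#' @param dataset_id Dataset label used in the template column.
#' @return List with `data_template` and `cutoff_template` paths.
#' @export
generate_templates <- function(spec, data_path, dir, dataset_id = "sim1") {
  stopifnot(inherits(spec, "sim_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cols <- sim_raw_columns(spec)
  bm <- data.frame(
    biomarker = c(names(spec$biomarker_params), "agp", "crp"),
    var = c(unname(cols$vars), "agp", "crp"),
    unit = c(unname(cols$units), "g/L", "mg/L"),
    stringsAsFactors = FALSE)
  desc <- dataset_descriptor(
    dataset_id = dataset_id, file_path = data_path,
    survey_design = list(stratum = "strat", cluster = "psu", weight = "wt"),
    age_var = if (spec$group == "PSC") "age_mo" else "age_y",
    age_unit = if (spec$group == "PSC") "months" else "years",
    sex_var = "sex", sex_coding = c(male = "1", female = "2"),
    population_group = spec$group, biomarkers = bm)
  dt_path <- file.path(dir, "dataset_template.csv")
  write_dataset_template(list(desc), dt_path)
  age <- if (spec$group == "PSC") c(6, 59, "months") else c(15, 49, "years")
  ct <- do.call(rbind, lapply(names(spec$truth_cutoffs), function(b) data.frame(
    biomarker = b, condition_label = paste0(b, "_deficiency"),
    group = spec$group, sex = "any",
    age_min = age[1], age_max = age[2], age_unit = age[3],
    direction = "below", threshold = spec$truth_cutoffs[[b]],
    threshold_unit = canonical_units()[[b]], use_adjusted = TRUE,
    source = "synthetic fixture", stringsAsFactors = FALSE)))
  ct_path <- file.path(dir, "cutoff_template.csv")
  utils::write.csv(ct, ct_path, row.names = FALSE, quote = TRUE)
  list(data_template = dt_path, cutoff_template = ct_path)
}
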