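# Regression-correction inflammation adjustment (BRINDA method).
#
# For an adjustable biomarker X with inflammation markers AGP and/or CRP,
# fit by OLS over complete cases
#   ln X = b0 + b1 ln AGP + b2 ln CRP + e
# and correct each observation above the reference level of a marker by
#   ln X_adj = ln X - b1 max(ln AGP - ref_agp, 0) - b2 max(ln CRP - ref_crp, 0)
# Reference values default to the lowest decile of the dataset's own
# ln-marker distribution; participants at or below reference are unchanged.

#' Configuration for the inflammation adjustment
#'
#' @param biomarkers Biomarkers eligible for adjustment; default ferritin,
#'   sTfR, RBP, retinol and zinc.
#' @param regressors Named list mapping biomarker to the inflammation
#'   markers used as regressors (subset of `c("agp","crp")`).  Default:
#'   both available markers, except sTfR which conventionally uses AGP
#'   only.
#' @param external_refs Optional named numeric vector with elements
#'   `ln_agp_ref` and/or `ln_crp_ref` (natural-log scale, SI units: g/L for
#'   AGP, mg/L for CRP).  When given, these replace the internal deciles.
#' @param min_n Minimum complete cases to attempt a fit (default 10);
#'   below it the biomarker is bypassed with a warning.
#' @param significance_gate If `TRUE`, slopes with p > 0.05 are set to 0
#'   before correction (default `FALSE`: slopes apply regardless of
#'   significance).
#' @param ref_prob Quantile used for internal references (default 0.10,
#'   the lowest decile).
#' @return An `adjust_config` list.
#' @export
adjust_config <- function(biomarkers = mn_adjustable_biomarkers(),
                          regressors = list(stfr = "agp"),
                          external_refs = NULL,
                          min_n = 10L,
                          significance_gate = FALSE,
                          ref_prob = 0.10) {
  structure(list(biomarkers = biomarkers, regressors = regressors,
                 external_refs = external_refs, min_n = as.integer(min_n),
                 significance_gate = isTRUE(significance_gate),
                 ref_prob = ref_prob),
            class = "adjust_config")
}

#' Lowest-decile reference values of the inflammation markers
#'
#' Computes the `ref_prob` quantile (default the 10th percentile, quantile
#' type 7) of `ln(AGP)` and `ln(CRP)` over non-missing positive values of
#' the dataset being adjusted.  A marker that is absent or has fewer than
#' `min_n` usable values yields an absent reference (with a warning in the
#' low-n case).
#'
#' @param ds A SI-converted `std_dataset`.
#' @param ref_prob Reference quantile probability.
#' @param min_n Minimum usable values per marker.
#' @return A `reference_values` list with `ln_agp_ref`, `ln_crp_ref`
#'   (either may be `NULL`) and `source`.
#' @export
compute_reference_deciles <- function(ds, ref_prob = 0.10, min_n = 10L) {
  stopifnot(inherits(ds, "std_dataset"))
  one <- function(marker) {
    if (!marker %in% names(ds$data)) return(NULL)
    v <- ds$data[[marker]]
    v <- v[!is.na(v) & v > 0]
    if (length(v) < min_n) {
      warning(sprintf(
        "marker '%s' has only %d usable value(s) (< %d); reference not computed",
        marker, length(v), min_n))
      return(NULL)
    }
    unname(stats::quantile(log(v), probs = ref_prob, type = 7))
  }
  structure(list(ln_agp_ref = one("agp"), ln_crp_ref = one("crp"),
                 source = "internal_decile"),
            class = "reference_values")
}

#' @export
print.reference_values <- function(x, ...) {
  cat("<reference_values>", x$source, "\n")
  if (!is.null(x$ln_agp_ref))
    cat(sprintf("  ln AGP ref = %.4f (AGP %.3f g/L)\n", x$ln_agp_ref,
                exp(x$ln_agp_ref)))
  if (!is.null(x$ln_crp_ref))
    cat(sprintf("  ln CRP ref = %.4f (CRP %.3f mg/L)\n", x$ln_crp_ref,
                exp(x$ln_crp_ref)))
  invisible(x)
}

bypass_model <- function(biomarker, reason) {
  structure(list(biomarker = biomarker, beta0 = NA_real_, beta1 = NULL,
                 beta2 = NULL, refs = NULL, n_fit = 0L, bypassed = TRUE,
                 reason = reason),
            class = "inflammation_model")
}

#' Fit the log-log inflammation regression for one biomarker
#'
#' Unweighted OLS of `ln(biomarker)` on the available regressors among
#' `ln(AGP)` and `ln(CRP)` over complete cases.  The regression targets the
#' biological ln-ln association, so survey weights are deliberately not
#' used.  Degenerate fits (fewer than `min_n` complete cases, or a constant
#' regressor making the design singular) return a bypassed model with a
#' reason instead of an error.
#'
#' @param ds A SI-converted `std_dataset`.
#' @param biomarker Canonical biomarker name to adjust.
#' @param refs A `reference_values` object (stored with the model).
#' @param regressors Markers to use, subset of `c("agp", "crp")`; default
#'   all markers present with a reference value.
#' @param min_n Minimum complete cases.
#' @param significance_gate Zero out slopes with p > 0.05.
#' @return An `inflammation_model` with `beta0`, `beta1` (ln AGP slope or
#'   `NULL`), `beta2` (ln CRP slope or `NULL`), `refs`, `n_fit`,
#'   `bypassed`, `reason`.
#' @export
fit_inflammation_regression <- function(ds, biomarker,
                                        refs = compute_reference_deciles(ds),
                                        regressors = NULL,
                                        min_n = 10L,
                                        significance_gate = FALSE) {
  stopifnot(inherits(ds, "std_dataset"))
  if (!biomarker %in% names(ds$data))
    return(bypass_model(biomarker, sprintf("biomarker '%s' not present", biomarker)))
  avail <- c(if (!is.null(refs$ln_agp_ref) && "agp" %in% names(ds$data)) "agp",
             if (!is.null(refs$ln_crp_ref) && "crp" %in% names(ds$data)) "crp")
  use <- if (is.null(regressors)) avail else intersect(regressors, avail)
  if (length(use) == 0L)
    return(bypass_model(biomarker, "no inflammation marker available"))
  y <- ds$data[[biomarker]]
  X <- lapply(use, function(m) ds$data[[m]])
  names(X) <- use
  ok <- !is.na(y) & y > 0
  for (m in use) ok <- ok & !is.na(X[[m]]) & X[[m]] > 0
  if (sum(ok) < min_n)
    return(bypass_model(biomarker, sprintf(
      "only %d complete case(s) (< %d)", sum(ok), min_n)))
  df <- data.frame(ln_y = log(y[ok]))
  for (m in use) df[[paste0("ln_", m)]] <- log(X[[m]][ok])
  sds <- vapply(use, function(m) stats::sd(df[[paste0("ln_", m)]]), numeric(1))
  if (any(sds == 0))
    return(bypass_model(biomarker, "singular design (constant regressor)"))
  fit <- stats::lm(stats::reformulate(paste0("ln_", use), response = "ln_y"),
                   data = df)
  if (any(is.na(stats::coef(fit))))
    return(bypass_model(biomarker, "singular design (collinear regressors)"))
  cf <- stats::coef(fit)
  pv <- summary(fit)$coefficients[, "Pr(>|t|)"]
  slope <- function(m) {
    nm <- paste0("ln_", m)
    if (!nm %in% names(cf)) return(NULL)
    b <- unname(cf[[nm]])
    if (significance_gate && pv[[nm]] > 0.05) 0 else b
  }
  structure(list(biomarker = biomarker, beta0 = unname(cf[["(Intercept)"]]),
                 beta1 = slope("agp"), beta2 = slope("crp"),
                 refs = refs, n_fit = sum(ok), bypassed = FALSE, reason = NULL),
            class = "inflammation_model")
}

#' @export
print.inflammation_model <- function(x, ...) {
  if (x$bypassed) {
    cat(sprintf("<inflammation_model> %s: bypassed (%s)\n", x$biomarker, x$reason))
  } else {
    cat(sprintf("<inflammation_model> ln(%s) ~ %.4f", x$biomarker, x$beta0))
    if (!is.null(x$beta1)) cat(sprintf(" + %.4f ln(AGP)", x$beta1))
    if (!is.null(x$beta2)) cat(sprintf(" + %.4f ln(CRP)", x$beta2))
    cat(sprintf("  [n = %d]\n", x$n_fit))
  }
  invisible(x)
}

#' Apply the regression correction to one biomarker
#'
#' For each row with an observed biomarker value, subtracts on the ln scale
#' the fitted inflammation contribution above reference:
#' `ln x_adj = ln x - beta1 * max(ln AGP - ref, 0) - beta2 * max(ln CRP - ref, 0)`,
#' a term being dropped when its marker or slope is absent from the model.
#' Rows at or below reference on all modelled markers are numerically
#' unchanged.  Rows missing a modelled inflammation marker are not
#' adjusted: their adjusted value is `NA` and they are flagged.
#'
#' @param ds A SI-converted `std_dataset`.
#' @param model An `inflammation_model` fitted on the same dataset.
#' @return List with `adjusted` (numeric vector, SI units), `not_adjusted`
#'   (logical: observed rows left unadjusted for missing markers) and
#'   `model`.
#' @export
apply_regression_correction <- function(ds, model) {
  stopifnot(inherits(ds, "std_dataset"), inherits(model, "inflammation_model"))
  x <- ds$data[[model$biomarker]]
  n <- length(x)
  if (model$bypassed)
    return(list(adjusted = rep(NA_real_, n), not_adjusted = !is.na(x),
                model = model))
  ln_adj <- log(x)
  needed_ok <- rep(TRUE, n)
  term <- function(marker, beta, ref) {
    if (is.null(beta)) return(NULL)
    v <- ds$data[[marker]]
    needed_ok <<- needed_ok & !is.na(v) & v > 0
    beta * pmax(log(pmax(v, 1e-300)) - ref, 0)
  }
  t1 <- term("agp", model$beta1, model$refs$ln_agp_ref)
  t2 <- term("crp", model$beta2, model$refs$ln_crp_ref)
  if (!is.null(t1)) ln_adj <- ln_adj - ifelse(needed_ok, t1, NA_real_)
  if (!is.null(t2)) ln_adj <- ln_adj - ifelse(needed_ok, t2, NA_real_)
  adjusted <- exp(ln_adj)
  adjusted[!needed_ok] <- NA_real_
  list(adjusted = adjusted,
       not_adjusted = !is.na(x) & !needed_ok,
       model = model)
}

#' Inflammation-adjust a dataset (BRINDA regression correction)
#'
#' Orchestrates reference-decile computation and per-biomarker fitting and
#' correction for the adjustable biomarkers present in the dataset.  The
#' whole step is bypassed — the pipeline proceeds with unadjusted values —
#' when the dataset's population group is not PSC or WRA, or when neither
#' AGP nor CRP is available.
#'
#' @param ds A SI-converted `std_dataset` (zeros already recoded).
#' @param config An [adjust_config()].
#' @return An `adjustment_result`: list with `bypassed`, `reason`,
#'   `adjusted` (data frame of `<biomarker>_adj` columns, SI units),
#'   `not_adjusted` (logical data frame), `models` (per biomarker),
#'   `refs`.
#' @export
adjust_dataset <- function(ds, config = adjust_config()) {
  stopifnot(inherits(ds, "std_dataset"))
  if (!isTRUE(ds$si_converted))
    mn_validation_error("adjust_dataset requires an SI-converted dataset")
  n <- nrow(ds$data)
  bypass <- function(reason) {
    structure(list(bypassed = TRUE, reason = reason,
                   adjusted = data.frame(row_id = ds$data$row_id),
                   not_adjusted = data.frame(row_id = ds$data$row_id),
                   models = list(), refs = NULL),
              class = "adjustment_result")
  }
  grp <- ds$descriptor$population_group %||% "other"
  if (!grp %in% c("PSC", "WRA"))
    return(bypass(sprintf("population group '%s' is not PSC or WRA", grp)))
  if (!any(c("agp", "crp") %in% names(ds$data)))
    return(bypass("neither AGP nor CRP present"))
  if (!is.null(config$external_refs)) {
    er <- config$external_refs
    refs <- structure(list(
      ln_agp_ref = if ("ln_agp_ref" %in% names(er)) unname(er[["ln_agp_ref"]]),
      ln_crp_ref = if ("ln_crp_ref" %in% names(er)) unname(er[["ln_crp_ref"]]),
      source = "user_supplied"), class = "reference_values")
  } else {
    refs <- compute_reference_deciles(ds, config$ref_prob, config$min_n)
  }
  if (is.null(refs$ln_agp_ref) && is.null(refs$ln_crp_ref))
    return(bypass("no usable inflammation marker (references unavailable)"))
  todo <- intersect(config$biomarkers, names(ds$units))
  adjusted <- data.frame(row_id = ds$data$row_id)
  flags <- data.frame(row_id = ds$data$row_id)
  models <- list()
  for (bm in todo) {
    model <- fit_inflammation_regression(
      ds, bm, refs = refs,
      regressors = config$regressors[[bm]],
      min_n = config$min_n,
      significance_gate = config$significance_gate)
    models[[bm]] <- model
    if (model$bypassed) {
      warning(sprintf("dataset '%s': biomarker '%s' not adjusted: %s",
                      ds$dataset_id, bm, model$reason))
      next
    }
    res <- apply_regression_correction(ds, model)
    adjusted[[paste0(bm, "_adj")]] <- res$adjusted
    flags[[paste0(bm, "_not_adjusted")]] <- res$not_adjusted
  }
  if (length(models) && all(vapply(models, function(m) m$bypassed, logical(1))))
    return(bypass("no biomarker could be adjusted"))
  structure(list(bypassed = FALSE, reason = NULL, adjusted = adjusted,
                 not_adjusted = flags, models = models, refs = refs),
            class = "adjustment_result")
}

#' @export
print.adjustment_result <- function(x, ...) {
  if (x$bypassed) {
    cat(sprintf("<adjustment_result> bypassed: %s\n", x$reason))
  } else {
    cat("<adjustment_result> adjusted:",
        paste(sub("_adj$", "", setdiff(names(x$adjusted), "row_id")),
              collapse = ", "), "\n")
    for (m in x$models) print(m)
  }
  invisible(x)
}
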