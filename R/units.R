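#' Canonical SI units for the built-in biomarkers
#'
#' Each biomarker handled by the pipeline has exactly one canonical SI unit;
#' all analysis (adjustment, cutoff classification, summary statistics) is
#' done on that scale.
#'
#' @return Named character vector mapping canonical biomarker name to its SI
#'   unit string: ferritin `ug/L`; sTfR `mg/L`; RBP and retinol `umol/L`;
#'   zinc `umol/L`; serum and RBC folate `nmol/L`; vitamin B-12 `pmol/L`;
#'   AGP `g/L`; CRP `mg/L`.
#' @export
canonical_units <- function() {
  c(ferritin = "ug/L", stfr = "mg/L", rbp = "umol/L", retinol = "umol/L",
    zinc = "umol/L", folate_serum = "nmol/L", folate_rbc = "nmol/L",
    b12 = "pmol/L", agp = "g/L", crp = "mg/L")
}

# Molar masses (g/mol) backing the mass -> molar conversion factors.
# retinol C20H30O; zinc atomic; cyanocobalamin C63H88CoN14O14P;
# folic acid C19H19N7O6.
mn_molar_masses <- function() {
  c(retinol = 286.45, zinc = 65.38, b12 = 1355.37,
    folate_serum = 441.40, folate_rbc = 441.40)
}

new_registry <- function(entries, canonical) {
  structure(list(entries = entries, canonical = canonical),
            class = "conversion_registry")
}

#' Build the shipped unit-conversion registry
#'
#' The registry maps `(biomarker, source unit)` pairs to a positive factor
#' such that `value_SI = value_source * factor`.  Mass-to-molar factors are
#' constructed from molar masses as `scale / molar_mass` (e.g. retinol
#' ug/dL to umol/L is `10 / 286.45`), so their dimensional consistency is a
#' checkable identity, not a transcribed constant.  Every biomarker carries
#' the identity conversion from its canonical unit.  No conversion is
#' shipped for sTfR other than the identity: sTfR assays are not mutually
#' calibrated, so a molar conversion must be registered explicitly by the
#' user with [register_conversion()].
#'
#' @return A `conversion_registry` object.
#' @export
si_registry <- function() {
  canon <- canonical_units()
  mm <- mn_molar_masses()
  # identity entries: canonical unit -> itself, factor exactly 1
  ent <- data.frame(
    biomarker = names(canon), from_unit = unname(canon),
    to_unit = unname(canon), factor = 1,
    scale = 1, molar_mass = NA_real_, stringsAsFactors = FALSE
  )
  add <- function(bm, from, scale, molar = NA_real_) {
    f <- if (is.na(molar)) scale else scale / molar
    data.frame(biomarker = bm, from_unit = from, to_unit = canon[[bm]],
               factor = f, scale = scale, molar_mass = molar,
               stringsAsFactors = FALSE)
  }
  ent <- rbind(
    ent,
    add("ferritin", "ng/mL", 1),              # ng/mL is ug/L
    add("retinol", "ug/dL", 10, mm[["retinol"]]),
    add("zinc", "ug/dL", 10, mm[["zinc"]]),
    add("b12", "pg/mL", 1000, mm[["b12"]]),
    add("folate_serum", "ng/mL", 1000, mm[["folate_serum"]]),
    add("folate_rbc", "ng/mL", 1000, mm[["folate_rbc"]]),
    add("crp", "mg/dL", 10),
    add("agp", "mg/dL", 0.01)
  )
  rownames(ent) <- NULL
  new_registry(ent, canon)
}

registry_key <- function(biomarker, unit) {
  paste(biomarker, norm_unit(unit), sep = "\r")
}

lookup_conversion <- function(registry, biomarker, unit) {
  e <- registry$entries
  hit <- e$biomarker == biomarker & norm_unit(e$from_unit) == norm_unit(unit)
  if (!any(hit)) return(NULL)
  e[which(hit)[1L], , drop = FALSE]
}

#' Add a unit conversion to a registry
#'
#' Used to support user-added biomarkers (any binary-outcome biomarker can
#' be analysed once its units and cutoffs are declared) or additional source
#' units for the built-in ones.  Re-registering an identical entry is a
#' no-op; registering the same `(biomarker, from_unit)` pair with a
#' different factor is an error.
#'
#' @param registry A `conversion_registry`.
#' @param biomarker Canonical biomarker name the conversion applies to.
#' @param from_unit Source unit string.
#' @param to_unit Target unit; must equal the biomarker's canonical unit if
#'   one is already registered, otherwise it becomes the canonical unit.
#' @param factor Positive multiplier: `value_target = value_source * factor`.
#' @return The updated registry.
#' @export
register_conversion <- function(registry, biomarker, from_unit, to_unit, factor) {
  stopifnot(inherits(registry, "conversion_registry"))
  if (!is_scalar_chr(biomarker) || !nzchar(biomarker))
    mn_validation_error("biomarker name must be a non-empty string")
  if (!is_scalar_num(factor) || factor <= 0)
    mn_validation_error(sprintf(
      "conversion factor for %s %s must be a positive number (got %s)",
      biomarker, from_unit, format(factor)))
  canon <- registry$canonical
  if (biomarker %in% names(canon)) {
    if (norm_unit(to_unit) != norm_unit(canon[[biomarker]]))
      mn_validation_error(sprintf(
        "to_unit '%s' differs from the canonical unit '%s' for %s",
        to_unit, canon[[biomarker]], biomarker))
  } else {
    canon[biomarker] <- to_unit
    # new biomarker: give it its identity conversion as well
    registry$entries <- rbind(registry$entries, data.frame(
      biomarker = biomarker, from_unit = to_unit, to_unit = to_unit,
      factor = 1, scale = 1, molar_mass = NA_real_, stringsAsFactors = FALSE))
  }
  existing <- lookup_conversion(registry, biomarker, from_unit)
  if (!is.null(existing)) {
    if (isTRUE(all.equal(existing$factor, factor, tolerance = 1e-12)))
      return(new_registry(registry$entries, canon))
    mn_validation_error(sprintf(
      "conflicting conversion for %s '%s': registered factor %.12g, new factor %.12g",
      biomarker, from_unit, existing$factor, factor))
  }
  entries <- rbind(registry$entries, data.frame(
    biomarker = biomarker, from_unit = from_unit, to_unit = canon[[biomarker]],
    factor = factor, scale = NA_real_, molar_mass = NA_real_,
    stringsAsFactors = FALSE))
  rownames(entries) <- NULL
  new_registry(entries, canon)
}

#' Merge a user conversion file into a registry
#'
#' @param registry A `conversion_registry`.
#' @param path CSV file with columns `biomarker, from_unit, to_unit, factor`.
#' @return The updated registry.
#' @export
read_conversion_file <- function(registry, path) {
  if (!file.exists(path)) mn_io_error(sprintf("conversion file not found: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("biomarker", "from_unit", "to_unit", "factor")
  if (!all(need %in% names(tab)))
    mn_validation_error(sprintf("conversion file must have columns %s",
                                paste(need, collapse = ", ")))
  for (i in seq_len(nrow(tab))) {
    registry <- register_conversion(registry, tab$biomarker[i], tab$from_unit[i],
                                    tab$to_unit[i], as.numeric(tab$factor[i]))
  }
  registry
}

#' @export
print.conversion_registry <- function(x, ...) {
  cat(sprintf("<conversion_registry> %d entries, %d biomarkers\n",
              nrow(x$entries), length(x$canonical)))
  print(x$entries[, c("biomarker", "from_unit", "to_unit", "factor")],
        row.names = FALSE)
  invisible(x)
}

#' Convert a standardized dataset to SI units
#'
#' Multiplies every mapped biomarker and inflammation-marker column by its
#' registry factor and records the canonical unit.  All pairs are resolved
#' up front: an unknown `(biomarker, unit)` pair is an error before any
#' column is touched, so a dataset is never left half-converted.
#'
#' @param ds A `std_dataset` from [standardize()].
#' @param registry A `conversion_registry`; defaults to the shipped one.
#' @return The dataset with all biomarker columns on the SI scale and
#'   `units` updated; missing values stay missing.
#' @export
convert_to_si <- function(ds, registry = si_registry()) {
  stopifnot(inherits(ds, "std_dataset"))
  bms <- names(ds$units)
  conv <- vector("list", length(bms))
  names(conv) <- bms
  for (bm in bms) {
    hit <- lookup_conversion(registry, bm, ds$units[[bm]])
    if (is.null(hit))
      mn_validation_error(sprintf(
        "no conversion registered for biomarker '%s' from unit '%s'",
        bm, ds$units[[bm]]))
    conv[[bm]] <- hit
  }
  for (bm in bms) {
    ds$data[[bm]] <- ds$data[[bm]] * conv[[bm]]$factor
    ds$units[[bm]] <- conv[[bm]]$to_unit
  }
  ds$si_converted <- TRUE
  ds
}
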