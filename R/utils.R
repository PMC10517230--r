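#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

# Classed conditions so callers can distinguish validation failures
# (bad templates, bad units) from I/O failures (missing/corrupt files).
mn_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "mn_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

mn_validation_error <- function(msg) mn_stop(msg, "mn_validation_error")
mn_io_error <- function(msg) mn_stop(msg, "mn_io_error")

# Unit strings are compared after normalization: surrounding whitespace
# stripped, micro sign and Greek mu mapped to "u", case folded.
norm_unit <- function(u) {
  u <- trimws(as.character(u))
  u <- gsub("µ|μ", "u", u)
  tolower(u)
}

# Canonical biomarker names recognised by the pipeline.  Arbitrary
# user-added biomarkers are allowed everywhere; these are the ones with
# shipped units, adjustment defaults and cutoff rules.
mn_known_biomarkers <- function() {
  c("ferritin", "stfr", "rbp", "retinol", "zinc",
    "folate_serum", "folate_rbc", "b12", "agp", "crp")
}

# Biomarkers eligible for BRINDA regression correction by default.
mn_adjustable_biomarkers <- function() {
  c("ferritin", "stfr", "rbp", "retinol", "zinc")
}

is_scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Full-precision, locale-independent number formatting for CSV output
# (deterministic across runs; round-trips doubles).
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else formatC(v, digits = 17, format = "g")
  }, character(1))
  out
}
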