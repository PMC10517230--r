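# Shared fixture builders and independent oracles.

# Build a standardized, SI-converted dataset through the public API:
# writes `df` to a temp CSV with canonical column names and loads it via a
# descriptor that maps each biomarker to itself in its canonical unit.
make_si_dataset <- function(df, biomarkers, group = "PSC",
                            design_cols = intersect(c("stratum", "cluster", "weight"),
                                                    names(df)),
                            id = "fix1") {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  units <- mnsurvey::canonical_units()
  bm <- data.frame(biomarker = biomarkers, var = biomarkers,
                   unit = unname(units[biomarkers]), stringsAsFactors = FALSE)
  design <- NULL
  if (length(design_cols) && "weight" %in% design_cols)
    design <- as.list(setNames(design_cols, design_cols))
  desc <- mnsurvey::dataset_descriptor(
    dataset_id = id, file_path = path,
    survey_design = design,
    age_var = if ("age" %in% names(df)) "age",
    age_unit = if ("age" %in% names(df)) {
      if (group == "PSC") "months" else "years"
    },
    sex_var = if ("sex" %in% names(df)) "sex",
    sex_coding = if ("sex" %in% names(df)) c(male = "1", female = "2"),
    population_group = group, biomarkers = bm)
  raw <- mnsurvey::load_raw(desc)
  ds <- mnsurvey::standardize(raw, desc)
  ds <- mnsurvey::recode_zeros(ds)
  mnsurvey::convert_to_si(ds)
}

# Independent brute-force evaluation of the stratified between-PSU
# linearized variance of the weighted mean: written from the definition
# with explicit loops, no shared code with the package internals.
oracle_mean_var <- function(y, w, stratum, cluster) {
  keep <- !is.na(y)
  y <- y[keep]; w <- w[keep]; stratum <- stratum[keep]; cluster <- cluster[keep]
  W <- sum(w)
  est <- sum(w * y) / W
  z <- w * (y - est) / W
  v <- 0
  df <- 0
  for (h in unique(stratum)) {
    rows_h <- which(stratum == h)
    psus <- unique(cluster[rows_h])
    nh <- length(psus)
    df <- df + nh
    tot <- numeric(nh)
    for (j in seq_along(psus)) tot[j] <- sum(z[rows_h][cluster[rows_h] == psus[j]])
    if (nh >= 2) v <- v + nh / (nh - 1) * sum((tot - mean(tot))^2)
  }
  list(estimate = est, var = v, se = sqrt(v), df = df - length(unique(stratum)))
}

# 16-row, 2 strata x 2 PSUs hand fixture used by several tests.
oracle_fixture <- function() {
  data.frame(
    stratum = rep(c("A", "B"), each = 8),
    cluster = rep(c("a1", "a2", "b1", "b2"), each = 4),
    weight = c(1, 2, 1, 2, 3, 1, 2, 1, 1, 1, 2, 2, 1, 3, 1, 2),
    y = c(10, 12, 9, 14, 11, 8, 13, 10, 20, 18, 22, 25, 19, 24, 21, 17),
    d = c(1, 0, 0, 1, 0, 0, 1, 0, 1, 1, 0, 1, 0, 1, 1, 0))
}
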