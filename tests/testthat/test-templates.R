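# Dataset-descriptor and cutoff template parsing and validation.

write_two_col_template <- function(path, with_design = TRUE) {
  d1 <- dataset_descriptor(
    dataset_id = "kenya_psc", file_path = "d1.csv",
    survey_design = if (with_design)
      list(stratum = "strat", cluster = "psu", weight = "wt"),
    age_var = "age_mo", age_unit = "months",
    sex_var = "sex", sex_coding = c(male = "1", female = "2"),
    population_group = "PSC",
    biomarkers = data.frame(biomarker = c("ferritin", "agp"),
                            var = c("FER", "agp"),
                            unit = c("ug/L", "g/L")))
  d2 <- dataset_descriptor(
    dataset_id = "us_wra", file_path = "d2.csv",
    age_var = "ridageyr", age_unit = "years",
    population_group = "WRA",
    biomarkers = data.frame(biomarker = "ferritin", var = "sf", unit = "ng/mL"))
  write_dataset_template(list(d1, d2), path)
  list(d1, d2)
}

test_that("a two-column template loads to two descriptors in column order", {
  path <- tempfile(fileext = ".csv")
  orig <- write_two_col_template(path)
  desc <- load_dataset_template(path)
  expect_length(desc, 2L)
  expect_identical(vapply(desc, `[[`, "", "dataset_id"), c("kenya_psc", "us_wra"))
  expect_identical(desc[[1]]$survey_design,
                   list(stratum = "strat", cluster = "psu", weight = "wt"))
  # optional fields that were not specified stay absent, not defaulted
  expect_null(desc[[2]]$survey_design)
  expect_null(desc[[2]]$sex_var)
  expect_identical(desc[[2]]$file_format, "auto")
})

test_that("writing descriptors and re-loading round-trips field-by-field", {
  path <- tempfile(fileext = ".csv")
  orig <- write_two_col_template(path)
  desc <- load_dataset_template(path)
  for (k in 1:2) {
    for (f in c("dataset_id", "file_format", "survey_design", "age_var",
                "age_unit", "sex_var", "sex_coding", "population_group",
                "biomarkers")) {
      expect_identical(desc[[k]][[f]], orig[[k]][[f]],
                       info = sprintf("descriptor %d field %s", k, f))
    }
    # file paths are resolved against the template directory on load
    expect_identical(basename(desc[[k]]$file_path), orig[[k]]$file_path)
  }
})

test_that("template validation rejects duplicate ids, bad units, bad rows", {
  tab <- data.frame(field = c("file", "ferritin_var", "ferritin_unit"),
                    ds1 = c("a.csv", "sf", "ug/L"),
                    ds2 = c("b.csv", "sf", "ug/L"))
  names(tab)[3] <- "ds1"  # duplicate dataset id
  p <- tempfile(fileext = ".csv")
  utils::write.csv(tab, p, row.names = FALSE)
  expect_error(load_dataset_template(p), "duplicated dataset_id 'ds1'",
               class = "mn_validation_error")

  # unit not registered for ferritin, error names both biomarker and unit
  tab2 <- data.frame(field = c("file", "ferritin_var", "ferritin_unit"),
                     ds1 = c("a.csv", "sf", "mg/dL"))
  utils::write.csv(tab2, p, row.names = FALSE)
  err <- tryCatch(load_dataset_template(p), error = identity)
  expect_s3_class(err, "mn_validation_error")
  expect_match(conditionMessage(err), "ferritin")
  expect_match(conditionMessage(err), "mg/dL")

  tab3 <- data.frame(field = c("file", "wieght"), ds1 = c("a.csv", "w"))
  utils::write.csv(tab3, p, row.names = FALSE)
  expect_error(load_dataset_template(p), "unknown template field",
               class = "mn_validation_error")

  expect_error(load_dataset_template(tempfile()), "not found",
               class = "mn_io_error")

  # design without a weight variable is rejected
  expect_error(dataset_descriptor("x", "f.csv",
                                  survey_design = list(stratum = "s")),
               "weight", class = "mn_validation_error")
})

test_that("the packaged cutoff table resolves the standard thresholds", {
  ct <- load_cutoff_template()
  r <- lookup_cutoff(ct, "ferritin", "PSC", age = 24, age_unit = "months",
                     condition_label = "iron_deficiency")
  expect_equal(nrow(r), 1L)
  expect_identical(r$direction, "below")
  expect_equal(r$threshold, 12)
  expect_identical(r$threshold_unit, "ug/L")
  expect_true(r$use_adjusted)

  r <- lookup_cutoff(ct, "ferritin", "WRA", age = 30, age_unit = "years",
                     condition_label = "iron_deficiency")
  expect_equal(r$threshold, 15)

  r <- lookup_cutoff(ct, "retinol", "PSC", age = 24, age_unit = "months")
  expect_equal(r$threshold, 0.7)
  expect_true(r$use_adjusted)
  # vitamin A for women of reproductive age is assessed on unadjusted retinol
  r <- lookup_cutoff(ct, "retinol", "WRA", age = 30, age_unit = "years")
  expect_false(r$use_adjusted)
})

test_that("cutoff thresholds are converted to SI on load", {
  p <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(
    biomarker = "retinol", condition_label = "vad", group = "PSC", sex = "any",
    age_min = 6, age_max = 59, age_unit = "months", direction = "below",
    threshold = 20.0515, threshold_unit = "ug/dL", use_adjusted = TRUE,
    source = ""), p, row.names = FALSE)
  ct <- load_cutoff_template(p)
  expect_equal(ct$threshold, 20.0515 * 10 / 286.45)
  expect_identical(ct$threshold_unit, "umol/L")
})

test_that("overlapping and malformed cutoff rules are rejected", {
  base <- data.frame(
    biomarker = "zinc", condition_label = "zinc_deficiency", group = "WRA",
    sex = "any", age_min = c(15, 25), age_max = c(30, 49),
    age_unit = "years", direction = "below", threshold = 10,
    threshold_unit = "umol/L", use_adjusted = TRUE, source = "")
  p <- tempfile(fileext = ".csv")
  utils::write.csv(base, p, row.names = FALSE)
  expect_error(load_cutoff_template(p), "rows 1 and 2",
               class = "mn_validation_error")

  base$age_max <- c(24, 49)  # disjoint closed intervals must pass
  utils::write.csv(base, p, row.names = FALSE)
  expect_s3_class(load_cutoff_template(p), "cutoff_table")

  base$threshold <- c(-1, 10)
  expect_error({
    utils::write.csv(base, p, row.names = FALSE)
    load_cutoff_template(p)
  }, "threshold", class = "mn_validation_error")
})

test_that("an empty rules file yields an empty table and no deficiency columns", {
  p <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(
    biomarker = character(), condition_label = character(), group = character(),
    sex = character(), age_min = numeric(), age_max = numeric(),
    age_unit = character(), direction = character(), threshold = numeric(),
    threshold_unit = character(), use_adjusted = logical(), source = character()),
    p, row.names = FALSE)
  ct <- load_cutoff_template(p)
  expect_equal(nrow(ct), 0L)
  ds <- make_si_dataset(
    data.frame(age = 24, sex = 1, ferritin = 10), "ferritin")
  calls <- classify_deficiency(ds, NULL, ct)
  expect_equal(nrow(calls), 0L)
  out <- tempfile(fileext = ".csv")
  write_clean_dataset(ds, NULL, calls, out)
  expect_false(any(grepl("^def_", names(read_clean_dataset(out)))))
})

test_that("cutoff lookup resolves to at most one rule per condition over a grid", {
  ct <- load_cutoff_template()
  ages_m <- seq(0, 720, by = 3)
  worst <- 0L
  for (bm in unique(ct$biomarker)) {
    conds <- unique(ct$condition_label[ct$biomarker == bm])
    for (grp in c("PSC", "WRA", "other")) for (sx in c("male", "female")) {
      for (a in ages_m) {
        hits <- lookup_cutoff(ct, bm, grp, age = a, age_unit = "months", sex = sx)
        worst <- max(worst,
                     max(table(factor(hits$condition_label, levels = conds))))
      }
    }
  }
  expect_lte(worst, 1L)
})

test_that("validate_templates reports unmapped cutoffs and inapplicable groups", {
  d <- dataset_descriptor(
    "ds1", "f.csv", population_group = "PSC",
    age_var = "age", age_unit = "months",
    biomarkers = data.frame(biomarker = "ferritin", var = "sf", unit = "ug/L"))
  ct <- load_cutoff_template()
  rep <- validate_templates(list(d), ct)
  expect_true(any(grepl("zinc", rep$message)))
  expect_true(all(rep$severity == "warning"))

  # population_group 'other' with a group-specific table: warn that no rule applies
  d2 <- dataset_descriptor(
    "ds2", "f.csv", population_group = "other",
    age_var = "age", age_unit = "years",
    biomarkers = data.frame(biomarker = "ferritin", var = "sf", unit = "ug/L"))
  rep2 <- validate_templates(list(d2), ct)
  expect_true(any(rep2$field == "population_group"))

  # fully matching templates produce an empty report
  spec <- sim_spec(seed = 3)
  g <- generate_survey_dataset(spec, tempdir(), name = "vt")
  tp <- generate_templates(spec, g$paths[["csv"]], tempdir())
  rep3 <- validate_templates(load_dataset_template(tp$data_template),
                             load_cutoff_template(tp$cutoff_template))
  expect_equal(nrow(rep3), 0L)
})
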