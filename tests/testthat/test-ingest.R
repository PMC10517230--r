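# Loading, pre-analysis error checking, standardization and zero recode.

tiny_descriptor <- function(path, format = "auto", weight_var = NULL) {
  dataset_descriptor(
    dataset_id = "t1", file_path = path, file_format = format,
    survey_design = if (!is.null(weight_var)) list(weight = weight_var),
    age_var = "age_mo", age_unit = "months",
    sex_var = "sex", sex_coding = c(male = "1", female = "2"),
    population_group = "PSC",
    biomarkers = data.frame(biomarker = c("ferritin", "agp"),
                            var = c("FER", "agp"),
                            unit = c("ug/L", "g/L")))
}

tiny_table <- function(n = 10) {
  set.seed(42)
  data.frame(age_mo = sample(6:59, n, replace = TRUE),
             sex = sample(1:2, n, replace = TRUE),
             FER = round(exp(rnorm(n, log(30), 0.7)), 3),
             agp = round(exp(rnorm(n, log(0.8), 0.4)), 3),
             wt = round(runif(n, 1, 3), 3),
             extra = letters[seq_len(n)])
}

test_that("load_raw preserves a CSV verbatim and rejects empty files", {
  tab <- tiny_table(100)
  p <- tempfile(fileext = ".csv")
  utils::write.csv(tab, p, row.names = FALSE)
  raw <- load_raw(tiny_descriptor(p))
  expect_equal(raw$n_rows, 100L)
  expect_equal(ncol(raw$table), 6L)
  expect_equal(raw$table$FER, tab$FER)
  expect_identical(raw$table$extra, tab$extra)

  utils::write.csv(tab[0, ], p, row.names = FALSE)
  expect_error(load_raw(tiny_descriptor(p)), "empty dataset",
               class = "mn_io_error")
  expect_error(load_raw(tiny_descriptor(tempfile(fileext = ".csv"))),
               "not found", class = "mn_io_error")
})

test_that("the same content loads identically from every supported format", {
  tab <- tiny_table(25)
  paths <- c(csv = tempfile(fileext = ".csv"),
             excel = tempfile(fileext = ".xlsx"),
             sas = tempfile(fileext = ".xpt"),
             spss = tempfile(fileext = ".sav"),
             stata = tempfile(fileext = ".dta"))
  utils::write.csv(tab, paths["csv"], row.names = FALSE)
  write_minimal_xlsx(tab, paths["excel"])
  haven::write_xpt(tab, paths["sas"])
  haven::write_sav(tab, paths["spss"])
  haven::write_dta(tab, paths["stata"])
  ref <- load_raw(tiny_descriptor(paths["csv"]))$table
  for (fmt in names(paths)[-1]) {
    got <- load_raw(tiny_descriptor(paths[[fmt]]))$table
    for (col in c("age_mo", "sex", "FER", "agp", "wt"))
      expect_equal(as.numeric(got[[col]]), as.numeric(ref[[col]]),
                   tolerance = 0, info = paste(fmt, col))
    expect_identical(as.character(got$extra), as.character(ref$extra))
  }
})

test_that("check_errors flags missing variables, bad weights, bad coding", {
  tab <- tiny_table()
  p <- tempfile(fileext = ".csv")
  utils::write.csv(tab, p, row.names = FALSE)
  raw <- load_raw(tiny_descriptor(p))

  # mapped column absent from the data
  d_missing <- dataset_descriptor(
    "t1", p, biomarkers = data.frame(biomarker = "ferritin", var = "sf",
                                     unit = "ug/L"))
  rep <- check_errors(raw, d_missing)
  expect_true(rep$is_fatal)
  expect_match(rep$items$message[1], "'sf' not found")

  # zero weight
  tab2 <- tab; tab2$wt[3] <- 0
  utils::write.csv(tab2, p, row.names = FALSE)
  rep <- check_errors(load_raw(tiny_descriptor(p, weight_var = "wt")),
                      tiny_descriptor(p, weight_var = "wt"))
  expect_true(rep$is_fatal)
  expect_true(any(grepl("non-positive", rep$items$message)))

  # sex outside declared coding
  tab3 <- tab; tab3$sex[2] <- 9
  utils::write.csv(tab3, p, row.names = FALSE)
  rep <- check_errors(load_raw(tiny_descriptor(p)), tiny_descriptor(p))
  expect_true(any(rep$items$field == "sex" & rep$items$severity == "error"))

  # two canonical names mapped to one source column
  d_dup <- dataset_descriptor(
    "t1", p, biomarkers = data.frame(biomarker = c("ferritin", "stfr"),
                                     var = c("FER", "FER"),
                                     unit = c("ug/L", "mg/L")))
  utils::write.csv(tab, p, row.names = FALSE)
  rep <- check_errors(load_raw(d_dup), d_dup)
  expect_true(any(grepl("more than one canonical", rep$items$message)))

  # implausible PSC age warns but is not fatal
  tab4 <- tab; tab4$age_mo[1] <- 100
  utils::write.csv(tab4, p, row.names = FALSE)
  rep <- check_errors(load_raw(tiny_descriptor(p)), tiny_descriptor(p))
  expect_true(any(rep$items$severity == "warning" & rep$items$field == "age"))
  expect_false(rep$is_fatal)

  # a fully valid mapping produces an empty report
  utils::write.csv(tab, p, row.names = FALSE)
  rep <- check_errors(load_raw(tiny_descriptor(p, weight_var = "wt")),
                      tiny_descriptor(p, weight_var = "wt"))
  expect_equal(nrow(rep$items), 0L)
  expect_false(rep$is_fatal)
})

test_that("check_errors never mutates the raw dataset", {
  tab <- tiny_table()
  p <- tempfile(fileext = ".csv")
  utils::write.csv(tab, p, row.names = FALSE)
  raw <- load_raw(tiny_descriptor(p))
  before <- raw$table
  invisible(check_errors(raw, tiny_descriptor(p)))
  expect_identical(raw$table, before)
})

test_that("standardize renames, recodes sex, keeps row order, drops unmapped", {
  tab <- tiny_table(30)
  p <- tempfile(fileext = ".csv")
  utils::write.csv(tab, p, row.names = FALSE)
  desc <- tiny_descriptor(p, weight_var = "wt")
  ds <- standardize(load_raw(desc), desc)
  expect_true("ferritin" %in% names(ds$data))
  expect_false("FER" %in% names(ds$data))
  expect_false("extra" %in% names(ds$data))
  expect_equal(ds$data$ferritin, tab$FER)          # row k in = row k out
  expect_identical(ds$data$sex,
                   ifelse(tab$sex == 1, "male", "female"))
  expect_equal(ds$data$age_months, as.numeric(tab$age_mo))
  expect_identical(unname(ds$units["ferritin"]), "ug/L")
  expect_false(ds$si_converted)
})

test_that("PSC ages declared in years are converted to months", {
  df <- data.frame(age_y = c(1, 2.5, 4), FER = c(10, 20, 30))
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE)
  desc <- dataset_descriptor(
    "t1", p, age_var = "age_y", age_unit = "years", population_group = "PSC",
    biomarkers = data.frame(biomarker = "ferritin", var = "FER", unit = "ug/L"))
  ds <- standardize(load_raw(desc), desc)
  expect_equal(ds$data$age_months, c(12, 30, 48))
})

test_that("declared sentinel codes become missing values", {
  df <- data.frame(FER = c("12.5", "-999", "30"), stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE)
  desc <- dataset_descriptor(
    "t1", p, biomarkers = data.frame(biomarker = "ferritin", var = "FER",
                                     unit = "ug/L"))
  ds <- standardize(load_raw(desc), desc, missing_codes = "-999")
  expect_equal(ds$data$ferritin, c(12.5, NA, 30))
})

test_that("recode_zeros maps exact zeros to 0.0001, flags them, is idempotent", {
  ds <- make_si_dataset(data.frame(ferritin = c(0, 5.2, NA, 0.0001)), "ferritin")
  # make_si_dataset already applies recode_zeros; inspect the result
  expect_equal(ds$data$ferritin, c(0.0001, 5.2, NA, 0.0001))
  expect_identical(ds$flags$zero_recoded_ferritin, c(TRUE, FALSE, FALSE, FALSE))
  again <- recode_zeros(ds)
  expect_identical(again$data, ds$data)
  expect_identical(again$flags, ds$flags)

  # a dataset without zeros is untouched
  ds2 <- make_si_dataset(data.frame(ferritin = c(3, 4.5)), "ferritin")
  expect_false(any(ds2$flags$zero_recoded_ferritin))
  expect_equal(ds2$data$ferritin, c(3, 4.5))
})
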