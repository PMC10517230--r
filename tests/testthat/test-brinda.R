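# BRINDA regression-correction inflammation adjustment.

# linear ln-ln data with known slopes, built through the public fixture path
brinda_fixture <- function(n, b1_fer = 0.8, b1_ret = -0.4, sd_fer = 0.1,
                           sd_ret = 0.1, seed = 101, crp = FALSE,
                           b2_fer = 0, b2_ret = 0) {
  set.seed(seed)
  ln_agp <- rnorm(n, log(0.8), 0.4)
  ln_crp <- rnorm(n, log(1.0), 1.0)
  df <- data.frame(
    agp = exp(ln_agp),
    ferritin = exp(3 + b1_fer * ln_agp + b2_fer * ln_crp + rnorm(n, 0, sd_fer)),
    retinol = exp(0.05 + b1_ret * ln_agp + b2_ret * ln_crp + rnorm(n, 0, sd_ret)))
  if (crp) df$crp <- exp(ln_crp)
  make_si_dataset(df, c("ferritin", "retinol", "agp", if (crp) "crp"))
}

test_that("reference deciles equal the declared quantile of ln markers", {
  grid <- exp(seq(-4, 1, length.out = 100))
  ds <- make_si_dataset(data.frame(crp = grid, agp = rep(0.8, 100)),
                        c("agp", "crp"))
  refs <- compute_reference_deciles(ds)
  # oracle: direct type-7 quantile of the ln values
  expect_equal(refs$ln_crp_ref,
               unname(quantile(seq(-4, 1, length.out = 100), 0.10, type = 7)),
               tolerance = 1e-12)
  # constant marker: reference is the constant itself
  expect_equal(refs$ln_agp_ref, log(0.8), tolerance = 1e-12)
  expect_identical(refs$source, "internal_decile")

  # absent marker gives an absent reference
  ds2 <- make_si_dataset(data.frame(agp = rep(0.8, 20)), "agp")
  refs2 <- compute_reference_deciles(ds2)
  expect_null(refs2$ln_crp_ref)
  expect_false(is.null(refs2$ln_agp_ref))

  # fewer than min_n usable values: absent with a warning
  ds3 <- make_si_dataset(data.frame(agp = c(rep(0.8, 5), rep(NA, 15))), "agp")
  expect_warning(refs3 <- compute_reference_deciles(ds3), "only 5")
  expect_null(refs3$ln_agp_ref)
})

test_that("the ln-ln regression recovers known slopes", {
  ds <- brinda_fixture(1000, sd_fer = 0.1)
  m <- fit_inflammation_regression(ds, "ferritin")
  expect_false(m$bypassed)
  # analytic slope SE at n=1000, residual sd 0.1, sd(lnAGP)=0.4 is ~0.008;
  # +/-0.03 is beyond 3 SE of the truth
  expect_equal(m$beta1, 0.8, tolerance = 0.03 / 0.8)
  expect_null(m$beta2)
  expect_equal(m$n_fit, 1000L)

  # independent oracle: lm on the same complete cases
  oracle <- unname(coef(lm(log(ds$data$ferritin) ~ log(ds$data$agp)))[2])
  expect_equal(m$beta1, oracle, tolerance = 1e-10)

  # under the null the slope estimate is near zero at n=5000
  set.seed(77)
  n <- 5000
  ds0 <- make_si_dataset(data.frame(
    agp = exp(rnorm(n, log(0.8), 0.4)),
    ferritin = exp(rnorm(n, 3, 0.5))), c("ferritin", "agp"))
  m0 <- fit_inflammation_regression(ds0, "ferritin")
  expect_lt(abs(m0$beta1), 0.05)
})

test_that("degenerate fits are bypassed with a reason, not an error", {
  ds <- make_si_dataset(data.frame(
    agp = rep(0.8, 50), ferritin = exp(rnorm(50, 3, 0.5))),
    c("ferritin", "agp"))
  m <- fit_inflammation_regression(ds, "ferritin")
  expect_true(m$bypassed)
  expect_match(m$reason, "singular design")

  ds2 <- brinda_fixture(30)
  ds2$data$ferritin[seq_len(25)] <- NA
  m2 <- fit_inflammation_regression(ds2, "ferritin")
  expect_true(m2$bypassed)
  expect_match(m2$reason, "complete case")
})

test_that("the correction matches its closed form and boundary behaviour", {
  # x = 30 ug/L, beta1 = 0.9, ln AGP - ref = 0.5, no CRP term:
  # adjusted = 30 * exp(-0.45) = 19.1335...
  ds <- make_si_dataset(data.frame(
    ferritin = c(30, 30, 30), agp = c(exp(0.5), 1, 0.5)), c("ferritin", "agp"))
  model <- structure(list(
    biomarker = "ferritin", beta0 = 3, beta1 = 0.9, beta2 = NULL,
    refs = structure(list(ln_agp_ref = 0, ln_crp_ref = NULL,
                          source = "user_supplied"),
                     class = "reference_values"),
    n_fit = 100L, bypassed = FALSE, reason = NULL),
    class = "inflammation_model")
  res <- apply_regression_correction(ds, model)
  expect_equal(res$adjusted[1], 30 * exp(-0.45), tolerance = 1e-12)
  # at the reference exactly, the term contributes zero
  expect_equal(res$adjusted[2], 30, tolerance = 1e-12)
  # below the reference, unchanged (max truncation)
  expect_equal(res$adjusted[3], 30, tolerance = 1e-12)

  # zero slopes: adjusted identical to unadjusted everywhere
  model$beta1 <- 0
  res0 <- apply_regression_correction(ds, model)
  expect_equal(res0$adjusted, ds$data$ferritin, tolerance = 1e-15)

  # a row missing its modelled marker is not adjusted and is flagged
  ds$data$agp[1] <- NA
  model$beta1 <- 0.9
  res_na <- apply_regression_correction(ds, model)
  expect_true(is.na(res_na$adjusted[1]))
  expect_true(res_na$not_adjusted[1])
})

test_that("adjust_dataset bypasses when inapplicable and adjusts otherwise", {
  # group outside PSC/WRA: full bypass
  df <- data.frame(agp = exp(rnorm(50, log(0.8), 0.4)))
  df$ferritin <- exp(3 + 0.8 * log(df$agp) + rnorm(50, 0, 0.2))
  ds_other <- make_si_dataset(df, c("ferritin", "agp"), group = "other")
  adj <- adjust_dataset(ds_other)
  expect_true(adj$bypassed)
  expect_match(adj$reason, "not PSC or WRA")

  # neither AGP nor CRP: full bypass, pipeline proceeds unadjusted
  ds_none <- make_si_dataset(data.frame(ferritin = exp(rnorm(50, 3, 0.5))),
                             "ferritin")
  adj2 <- adjust_dataset(ds_none)
  expect_true(adj2$bypassed)
  expect_match(adj2$reason, "neither AGP nor CRP")

  # ferritin + AGP only: adjusted with the AGP term alone
  ds_agp <- make_si_dataset(df, c("ferritin", "agp"))
  adj3 <- adjust_dataset(ds_agp)
  expect_false(adj3$bypassed)
  expect_false(is.null(adj3$models$ferritin$beta1))
  expect_null(adj3$models$ferritin$beta2)
  expect_true("ferritin_adj" %in% names(adj3$adjusted))
})

test_that("sTfR uses AGP only by default even when CRP is present", {
  set.seed(5)
  n <- 200
  ln_agp <- rnorm(n, log(0.8), 0.4); ln_crp <- rnorm(n, 0, 1)
  ds <- make_si_dataset(data.frame(
    agp = exp(ln_agp), crp = exp(ln_crp),
    stfr = exp(1.5 + 0.3 * ln_agp + 0.2 * ln_crp + rnorm(n, 0, 0.2)),
    ferritin = exp(3 + 0.8 * ln_agp + 0.2 * ln_crp + rnorm(n, 0, 0.2))),
    c("ferritin", "stfr", "agp", "crp"))
  adj <- adjust_dataset(ds)
  expect_null(adj$models$stfr$beta2)       # AGP only for sTfR
  expect_false(is.null(adj$models$ferritin$beta2))  # both for ferritin
})

test_that("adjustment direction follows the slope sign row-wise", {
  ds <- brinda_fixture(800, crp = TRUE, b2_fer = 0.25, b2_ret = -0.15,
                       sd_fer = 0.4, sd_ret = 0.2, seed = 11)
  adj <- adjust_dataset(ds)
  fer <- ds$data$ferritin; fer_a <- adj$adjusted$ferritin_adj
  ret <- ds$data$retinol; ret_a <- adj$adjusted$retinol_adj
  ok <- !is.na(fer_a)
  expect_true(all(fer_a[ok] <= fer[ok] + 1e-12))  # positive slopes shrink
  expect_true(all(ret_a[ok] >= ret[ok] - 1e-12))  # negative slopes raise
  expect_true(all(fer_a[ok] > 0))
  # rows at/below both references are exactly unchanged
  refs <- adj$refs
  below <- ok & log(ds$data$agp) <= refs$ln_agp_ref &
    log(ds$data$crp) <= refs$ln_crp_ref
  expect_gt(sum(below), 0)
  expect_equal(fer_a[below], fer[below], tolerance = 1e-12)
})

test_that("refitting the adjusted biomarker above reference removes the slope", {
  ds <- brinda_fixture(5000, sd_fer = 0.3, sd_ret = 0.25, seed = 202)
  adj <- adjust_dataset(ds)
  refs <- adj$refs
  above <- log(ds$data$agp) > refs$ln_agp_ref
  for (bm in c("ferritin", "retinol")) {
    y <- log(adj$adjusted[[paste0(bm, "_adj")]][above])
    x <- log(ds$data$agp[above])
    refit <- summary(lm(y ~ x))$coefficients
    expect_lt(abs(refit["x", "Estimate"]), 3 * refit["x", "Std. Error"])
  }
})

test_that("external reference values are honoured", {
  ds <- brinda_fixture(500, seed = 9)
  adj <- adjust_dataset(ds, adjust_config(
    external_refs = c(ln_agp_ref = log(0.6))))
  expect_identical(adj$refs$source, "user_supplied")
  expect_equal(adj$refs$ln_agp_ref, log(0.6))
  expect_null(adj$refs$ln_crp_ref)
})
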