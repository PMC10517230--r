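# Design-based estimation under stratified one-stage cluster sampling.
#
# Variance estimation is first-order Taylor linearization of the ratio
# estimator with the single-stage with-replacement approximation: for the
# weighted mean yhat = sum(w y) / sum(w), the linearized contribution of
# row i is z_i = w_i (y_i - yhat) / sum(w); PSU totals of z are formed
# within strata, and
#   var(yhat) = sum_h n_h / (n_h - 1) * sum_j (z_hj - zbar_h)^2
# with n_h the number of PSUs in stratum h.  Confidence intervals use a t
# reference with df = (#PSUs - #strata).  With unit weights, one stratum
# and each row its own PSU this reduces exactly to the textbook mean with
# SE = sd/sqrt(n) and df = n - 1.

#' Declare a survey design
#'
#' @param n Number of rows the design covers (required when all elements
#'   are defaults).
#' @param stratum Per-row stratum labels; default a single stratum.
#' @param cluster Per-row primary-sampling-unit labels; default each row is
#'   its own PSU.
#' @param weight Per-row positive sampling weights; default 1 (the
#'   simple-random-sampling reduction).
#' @return A `svy_design` object.
#' @export
svy_design <- function(n = NULL, stratum = NULL, cluster = NULL, weight = NULL) {
  n <- n %||% max(length(stratum), length(cluster), length(weight))
  if (n < 1L) mn_validation_error("svy_design needs n >= 1")
  stratum <- if (is.null(stratum)) rep("1", n) else as.character(stratum)
  cluster <- if (is.null(cluster)) as.character(seq_len(n)) else as.character(cluster)
  weight <- if (is.null(weight)) rep(1, n) else as.numeric(weight)
  if (length(stratum) != n || length(cluster) != n || length(weight) != n)
    mn_validation_error("stratum, cluster and weight must all have length n")
  if (any(is.na(weight) | weight <= 0))
    mn_validation_error("sampling weights must be positive and non-missing")
  # a PSU label must not span two strata; disambiguate by nesting
  cluster <- paste(stratum, cluster, sep = "\r")
  structure(list(stratum = stratum, cluster = cluster, weight = weight, n = n),
            class = "svy_design")
}

#' @export
print.svy_design <- function(x, ...) {
  cat(sprintf("<svy_design> %d rows, %d strata, %d PSUs, weight range [%g, %g]\n",
              x$n, length(unique(x$stratum)), length(unique(x$cluster)),
              min(x$weight), max(x$weight)))
  invisible(x)
}

design_subset <- function(design, keep) {
  structure(list(stratum = design$stratum[keep], cluster = design$cluster[keep],
                 weight = design$weight[keep], n = sum(keep)),
            class = "svy_design")
}

# Between-PSU within-stratum variance of a total of linearized values z.
# Returns list(var, df).  Lonely PSU: "error" (default) or "centered"
# (deviation taken from the grand mean of PSU totals).
taylor_var_total <- function(z, design, lonely = c("error", "centered")) {
  lonely <- match.arg(lonely)
  psu_tot <- rowsum(z, design$cluster, reorder = FALSE)[, 1L]
  psu_str <- design$stratum[!duplicated(design$cluster)]
  names(psu_str) <- design$cluster[!duplicated(design$cluster)]
  psu_str <- psu_str[names(psu_tot)]
  n_h <- table(psu_str)
  H <- length(n_h)
  df <- length(psu_tot) - H
  if (any(n_h < 2L)) {
    if (lonely == "error")
      mn_stop(sprintf(
        paste0("stratum '%s' has a single PSU; its variance contribution is ",
               "undefined. Collapse strata upstream or use lonely = 'centered'."),
        sub("\r.*$", "", names(n_h)[which(n_h < 2L)[1L]])), "mn_lonely_psu_error")
  }
  grand <- mean(psu_tot)
  v <- 0
  for (h in names(n_h)) {
    t_h <- psu_tot[psu_str == h]
    nh <- length(t_h)
    if (nh >= 2L) {
      v <- v + nh / (nh - 1) * sum((t_h - mean(t_h))^2)
    } else {
      v <- v + sum((t_h - grand)^2)  # centered lonely-PSU contribution
    }
  }
  list(var = v, df = df)
}

new_estimate <- function(statistic, estimate, se, ci_low, ci_high, n, n_weighted,
                         df = NA_real_) {
  structure(list(statistic = statistic, estimate = estimate, se = se,
                 ci_low = ci_low, ci_high = ci_high, n = n,
                 n_weighted = n_weighted, df = df),
            class = "svy_estimate")
}

#' @export
print.svy_estimate <- function(x, ...) {
  cat(sprintf("<svy_estimate> %s = %.6g", x$statistic, x$estimate))
  if (!is.na(x$se)) cat(sprintf(" (SE %.6g)", x$se))
  if (!is.na(x$ci_low)) cat(sprintf(", 95%% CI [%.6g, %.6g]", x$ci_low, x$ci_high))
  cat(sprintf(", n = %d\n", x$n))
  invisible(x)
}

#' @export
as.data.frame.svy_estimate <- function(x, ...) {
  data.frame(statistic = x$statistic, estimate = x$estimate, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, n = x$n,
             n_weighted = x$n_weighted, stringsAsFactors = FALSE)
}

complete_subset <- function(values, design) {
  keep <- !is.na(values)
  if (!any(keep)) mn_validation_error("all values are missing")
  list(y = values[keep], design = design_subset(design, keep))
}

#' Survey-weighted mean with Taylor-linearized SE
#'
#' @param values Per-row numeric values; missing values are dropped with
#'   their weights (complete-case).
#' @param design A [svy_design()]; defaults to SRS with unit weights.
#' @param conf_level Confidence level for the t interval.
#' @param lonely Handling of single-PSU strata: `"error"` or `"centered"`.
#' @return A `svy_estimate`.
#' @export
svy_mean <- function(values, design = svy_design(length(values)),
                     conf_level = 0.95, lonely = c("error", "centered")) {
  lonely <- match.arg(lonely)
  cs <- complete_subset(values, design)
  y <- cs$y; d <- cs$design
  W <- sum(d$weight)
  est <- sum(d$weight * y) / W
  z <- d$weight * (y - est) / W
  se <- NA_real_; lo <- NA_real_; hi <- NA_real_; df <- NA_real_
  vt <- taylor_var_total(z, d, lonely)
  df <- vt$df
  if (df > 0) {
    se <- sqrt(vt$var)
    tq <- stats::qt(1 - (1 - conf_level) / 2, df)
    lo <- est - tq * se
    hi <- est + tq * se
  } else {
    warning("design degrees of freedom <= 0; SE and CI not reported")
  }
  new_estimate("mean", est, se, lo, hi, length(y), W, df)
}

#' Survey-weighted geometric mean
#'
#' Computed as `exp` of the weighted mean of `ln(values)`; the CI is the
#' exponentiated ln-scale t interval and the natural-scale SE is obtained
#' by the delta method (`exp(m) * se_ln`).
#'
#' @inheritParams svy_mean
#' @return A `svy_estimate`.
#' @export
svy_geomean <- function(values, design = svy_design(length(values)),
                        conf_level = 0.95, lonely = c("error", "centered")) {
  lonely <- match.arg(lonely)
  if (any(!is.na(values) & values <= 0))
    mn_validation_error(
      "geometric mean requires strictly positive values (recode zeros upstream)")
  m <- svy_mean(log(values), design, conf_level, lonely)
  new_estimate("geometric_mean", exp(m$estimate),
               if (is.na(m$se)) NA_real_ else exp(m$estimate) * m$se,
               if (is.na(m$ci_low)) NA_real_ else exp(m$ci_low),
               if (is.na(m$ci_high)) NA_real_ else exp(m$ci_high),
               m$n, m$n_weighted, m$df)
}

# Weighted quantile point estimate: smallest distinct value whose
# cumulative weight fraction reaches p; when the fraction hits p exactly,
# the midpoint of the adjacent distinct values (the inverse weighted ECDF
# is between its left and right limits there).  Under unit weights this is
# quantile type 2.
weighted_quantile_point <- function(y, w, p) {
  o <- order(y)
  yo <- y[o]; wo <- w[o]
  agg <- rowsum(wo, yo, reorder = TRUE)
  vals <- as.numeric(rownames(agg))
  cw <- cumsum(agg[, 1L]) / sum(wo)
  j <- which(cw >= p - 1e-12)[1L]
  if (abs(cw[j] - p) <= 1e-12 && j < length(vals))
    (vals[j] + vals[j + 1L]) / 2
  else vals[j]
}

#' Survey-weighted quantile
#'
#' Point estimate from the weighted empirical CDF (see Details).  No SE is
#' reported by default; `woodruff = TRUE` adds a Woodruff confidence
#' interval (the CI of the estimated CDF at the quantile, inverted through
#' the weighted ECDF).
#'
#' @details The estimate is the smallest distinct data value whose
#'   cumulative weight fraction is at least `p`; if the fraction equals `p`
#'   exactly the midpoint of the two adjacent distinct values is returned.
#'   With unit weights this reproduces the textbook type-2 sample quantile.
#'
#' @inheritParams svy_mean
#' @param p Probability in (0, 1).
#' @param woodruff Report a Woodruff CI (default off).
#' @return A `svy_estimate` (statistic `q25`/`median`/`q75` for the common
#'   probabilities, otherwise `q<p>`).
#' @export
svy_quantile <- function(values, design = svy_design(length(values)), p = 0.5,
                         conf_level = 0.95, woodruff = FALSE,
                         lonely = c("error", "centered")) {
  lonely <- match.arg(lonely)
  if (!is_scalar_num(p) || p <= 0 || p >= 1)
    mn_validation_error("quantile probability p must be inside (0, 1)")
  cs <- complete_subset(values, design)
  y <- cs$y; d <- cs$design
  est <- weighted_quantile_point(y, d$weight, p)
  lab <- if (isTRUE(all.equal(p, 0.25))) "q25"
    else if (isTRUE(all.equal(p, 0.5))) "median"
    else if (isTRUE(all.equal(p, 0.75))) "q75"
    else sprintf("q%g", 100 * p)
  lo <- NA_real_; hi <- NA_real_
  if (woodruff) {
    ind <- as.numeric(y <= est)
    pm <- svy_mean(ind, d, conf_level, lonely)
    if (!is.na(pm$se)) {
      lo_p <- max(min(pm$estimate - (pm$estimate - pm$ci_low), 1), 0)
      hi_p <- max(min(pm$estimate + (pm$ci_high - pm$estimate), 1), 0)
      if (lo_p > 0) lo <- weighted_quantile_point(y, d$weight, lo_p)
      if (hi_p < 1) hi <- weighted_quantile_point(y, d$weight, hi_p)
    }
  }
  new_estimate(lab, est, NA_real_, lo, hi, length(y), sum(d$weight))
}

#' Survey-weighted prevalence (percent)
#'
#' The weighted mean of a 0/1 indicator expressed in percent, with the
#' Taylor-linearized SE of the mean and a Wald t interval truncated to
#' [0, 100].  `ci_method = "logit"` transforms the interval through the
#' logit scale instead.
#'
#' @param indicator Per-row values in {0, 1, NA}.
#' @inheritParams svy_mean
#' @param ci_method `"wald"` (default) or `"logit"`.
#' @return A `svy_estimate` with `estimate`, `se`, `ci_low`, `ci_high` on
#'   the percent scale.
#' @export
svy_prevalence <- function(indicator, design = svy_design(length(indicator)),
                           conf_level = 0.95, ci_method = c("wald", "logit"),
                           lonely = c("error", "centered")) {
  ci_method <- match.arg(ci_method)
  lonely <- match.arg(lonely)
  ok <- is.na(indicator) | indicator %in% c(0, 1)
  if (!all(ok)) mn_validation_error("indicator values must be 0, 1 or missing")
  m <- svy_mean(as.numeric(indicator), design, conf_level, lonely)
  p <- m$estimate
  lo <- m$ci_low; hi <- m$ci_high
  if (ci_method == "logit" && !is.na(m$se) && p > 0 && p < 1) {
    lg <- stats::qlogis(p)
    se_lg <- m$se / (p * (1 - p))
    tq <- stats::qt(1 - (1 - conf_level) / 2, m$df)
    lo <- stats::plogis(lg - tq * se_lg)
    hi <- stats::plogis(lg + tq * se_lg)
  }
  new_estimate("prevalence", 100 * p,
               if (is.na(m$se)) NA_real_ else 100 * m$se,
               if (is.na(lo)) NA_real_ else max(0, 100 * lo),
               if (is.na(hi)) NA_real_ else min(100, 100 * hi),
               m$n, m$n_weighted, m$df)
}
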