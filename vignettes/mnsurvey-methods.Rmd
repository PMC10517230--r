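---
title: "Methods: design-based micronutrient biomarker analysis with inflammation adjustment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design-based micronutrient biomarker analysis with inflammation adjustment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnsurvey)
```

# What the package computes

`mnsurvey` turns participant-level micronutrient biomarker surveys into
population summary statistics and deficiency-prevalence estimates. A run is
driven by two templates: a *dataset template* (one column per dataset, rows
for the file, survey-design variables, demographics, and each biomarker's
source column and unit) and a *cutoff template* (one row per deficiency
rule). The pipeline then proceeds through fixed stages: load, pre-analysis
error checks, name standardization, zero recode, SI unit conversion,
inflammation adjustment, cutoff classification, and design-based
estimation. Every stage is exposed as an ordinary function, and
`run_pipeline()` (or the `inst/cli/run_pipeline.R` script) chains them.

# Ingestion and standardization

Datasets may arrive as CSV, Excel (`.xlsx`), SAS (`.sas7bdat` or transport
`.xpt`), SPSS (`.sav`) or Stata (`.dta`); the format is auto-detected from
the extension unless declared. `check_errors()` audits the file against its
descriptor *before* any analysis: mapped variables must exist, numeric
columns must coerce, weights must be strictly positive, sex values must lie
in the declared coding, and ages are sanity-checked against the population
group (0–59 months for preschool-aged children, 10–60 years for women of
reproductive age; values outside warn rather than fail). Standardization
renames columns to canonical names, recodes sex to `male`/`female`,
converts PSC ages given in years to months (times 12, no rounding), and
preserves row order.

Two deliberate data-handling rules:

* **Zero recode.** Biomarker values of exactly 0 become 0.0001 so that log
  transformation is defined, and the row is flagged. The recode is applied
  in *source* units, before SI conversion, so the constant is always the
  printed 0.0001 regardless of unit scale. Negative values are never
  recoded — they are reported as errors.
* **Missingness.** Empty cells, declared sentinel codes and unparseable
  numerics become missing; every estimator is complete-case per biomarker.
  The package does no outlier removal and no limit-of-detection imputation;
  data are expected to be pre-cleaned.

# Unit conversion

Each biomarker has one canonical SI unit (ferritin µg/L; sTfR mg/L; RBP and
retinol µmol/L; zinc µmol/L; folate nmol/L; B-12 pmol/L; AGP g/L; CRP
mg/L). Conversions are multiplicative factors; mass→molar factors are
constructed as `scale / molar_mass` (retinol µg/dL→µmol/L is `10/286.45`,
zinc `10/65.38`, B-12 pg/mL→pmol/L `1000/1355.37`, folate ng/mL→nmol/L
`1000/441.40`), so each shipped factor satisfies the dimensional identity
`factor × molar_mass = scale` exactly — checked in the test suite rather
than transcribed. No molar conversion is shipped for sTfR because sTfR
assays are not mutually calibrated; users must register one explicitly
(`register_conversion()`), and unknown units always fail fast rather than
passing through.

# Inflammation adjustment (regression correction)

Ferritin, sTfR, RBP, retinol and zinc are confounded by inflammation. The
package implements the BRINDA regression-correction approach: for each
adjustable biomarker $X$, an unweighted OLS fit over complete cases of

$$\ln X = \beta_0 + \beta_1 \ln \mathrm{AGP} + \beta_2 \ln \mathrm{CRP} + \varepsilon$$

followed by the row-wise correction

$$\ln \tilde x_i = \ln x_i - \beta_1\,\max(\ln \mathrm{AGP}_i - a_{\mathrm{ref}}, 0)
 - \beta_2\,\max(\ln \mathrm{CRP}_i - c_{\mathrm{ref}}, 0),$$

with terms dropped when a marker or slope is absent. Reference values
default to the dataset's own lowest decile of the ln marker (quantile
type 7); externally supplied references are accepted through
`adjust_config()`. Design choices worth knowing:

* The `max(·, 0)` truncation means participants at or below the reference
  are numerically unchanged — low-inflammation individuals are never
  "negatively adjusted".
* sTfR is regressed on ln AGP only (the convention for that biomarker);
  the regressor set is configurable per biomarker.
* The regression is unweighted and ignores the survey design: it targets
  the biological ln–ln association, not a population parameter. This is a
  documented limitation, not an oversight.
* Slopes are applied regardless of significance (a significance gate is
  available but off by default), and a fit is attempted only with ≥ 10
  complete cases; anything degenerate (constant regressor, collinearity)
  bypasses with a recorded reason instead of failing the run.
* Folate and B-12 are not adjusted by default. The adjustable set is the
  five biomarkers above; the broader set sometimes discussed for this
  method can be enabled via `adjust_config(biomarkers = ...)`.
* Rows missing a modelled inflammation marker cannot be corrected; their
  adjusted value is missing and the row is flagged, rather than silently
  carrying an unadjusted number in an adjusted column.
* Adjustment runs only for PSC and WRA datasets; for any other population
  group the step is bypassed and unadjusted values flow through, because
  the correction's reference behaviour is established only for those
  groups.

# Design-based estimation

Estimators assume stratified one-stage cluster sampling with the
with-replacement approximation — the standard production-survey default.
For the weighted mean $\hat{\bar y} = \sum w_i y_i / \sum w_i$, the
linearized contribution of row $i$ is $z_i = w_i (y_i - \hat{\bar y}) /
\sum w_i$, PSU totals $z_{hj}$ are formed within strata, and

$$\widehat{\mathrm{Var}} = \sum_h \frac{n_h}{n_h - 1}
  \sum_j (z_{hj} - \bar z_h)^2 .$$

Confidence intervals use a t reference with design degrees of freedom
(number of PSUs minus number of strata). With unit weights, one stratum and
each row its own PSU, everything reduces exactly to the textbook
statistics: mean with SE $s/\sqrt n$, df $n-1$.

* **Geometric means** are `exp` of the ln-scale mean; the CI is the
  exponentiated ln-scale interval and the natural-scale SE is the delta
  method (`exp(m)·se_ln`).
* **Quantiles** use the weighted empirical CDF: the estimate is the
  smallest distinct value whose cumulative weight fraction reaches `p`,
  with the midpoint of adjacent distinct values at an exact crossing.
  Under unit weights this is the type-2 sample quantile. Quantile SEs are
  not reported by default; a Woodruff interval (CDF interval inverted
  through the weighted ECDF) is available.
* **Prevalence** is the weighted mean of the 0/1 indicator in percent,
  with a Wald t interval truncated to [0, 100] (logit-scale interval
  optional). Missing calls are excluded from the denominator, and the
  reported `n` makes the denominator auditable.
* **Lonely PSUs** (a stratum with a single PSU) are an error by default —
  silent misestimation is worse than failure — with an opt-in `centered`
  fallback that measures that stratum's PSU total against the grand mean.

Simulation evidence (recomputed by `scripts/acceptance.R` on every run)
puts the empirical coverage of the nominal 95% intervals for means and
prevalences at roughly 93–95% over 1000 stratified-cluster replicates of a
4-strata × 8-PSU × 15-row design: the linearization interval is mildly
anti-conservative at this many PSUs, which is the known behaviour of this
estimator class, and should be kept in mind for surveys with few clusters.

# Classification and reporting

Cutoff rules match on biomarker, population group, sex and a closed age
interval carried in each rule's own unit (months for PSC-style rules,
years for WRA-style rules); rules for the same condition must not overlap,
so a participant can match at most one rule per condition. Comparison is
strict: a value exactly at the threshold is *not* deficient, following the
"< 12 µg/L" convention in which thresholds are written. The shipped
default table encodes ferritin < 12 µg/L (PSC, adjusted) and < 15 µg/L
(WRA, adjusted), retinol < 0.7 µmol/L (adjusted for PSC, unadjusted for
WRA, following the convention used for those groups), an sTfR > 8.3 mg/L
rule flagged as assay-dependent, IZiNCG zinc thresholds and WHO folate/B-12
thresholds — every row carries a provenance note, and users override the
table by supplying their own file.

When adjustment ran, each distribution statistic and each prevalence is
reported on both the adjusted and unadjusted scale with an `adjusted` flag,
so the comparison needs no second run. Output CSVs serialize numbers at
full precision (plus 2-decimal display columns), use empty cells for absent
SEs, and contain no timestamps, so repeated runs on identical inputs are
byte-identical.

# The synthetic-data generator

`sim_spec()`/`simulate_survey()` generate stratified-cluster surveys with
known truth, used throughout the tests. Observed log-concentrations are
linear in the log inflammation markers:

$$\ln X = \mu + \delta_h + u_{\mathrm{PSU}} + b_1 \ln \mathrm{AGP}
  + b_2 \ln \mathrm{CRP} + \varepsilon,$$

with fixed stratum shifts $\delta_h$, a between-PSU random intercept, and
weights a deterministic function of stratum only (so design-based
estimators stay unbiased and analytic truths stay computable).

**What "inflammation-free" means here.** The truth sidecar stores
$X_{\mathrm{free}} = \exp(\ln X - b_1 (\ln \mathrm{AGP} - r_a)_+ -
b_2 (\ln \mathrm{CRP} - r_c)_+)$ with $r_a, r_c$ the *population* 10th
percentiles of the ln markers. That is, truth removes the above-baseline
part of the inflammation effect — the estimand a lowest-decile regression
correction targets. Defining truth as removal of the *entire* marker
association would make it unrecoverable by construction for any
reference-truncated correction (the below-reference share of the
association is deliberately left in place), so it would not be a meaningful
benchmark for this method. AGP is never zero in a living participant;
"free of inflammation" here means "at the healthy baseline level of the
acute-phase markers".

Default parameters describe a plausible high-burden PSC survey: ferritin
geometric mean 30 µg/L with ln-scale SD 0.7 and slopes 0.8 (ln AGP) and
0.25 (ln CRP); retinol geometric mean 1.05 µmol/L, SD 0.25, slopes −0.4
and −0.15; AGP around 0.8 g/L (ln SD 0.4), CRP around 1 mg/L (ln SD 1.0);
between-PSU ln-scale SD 0.2 (log-scale ICC ≈ 8% for ferritin); stratum
weight multipliers spanning 1–3. These are stylized magnitudes of the kind
reported for such surveys, not a reconstruction of any particular country
survey.

What the generator does *not* emulate — and therefore what passing tests do
not certify about real data: assay measurement error and limits of
detection, item nonresponse patterns correlated with status, multi-stage
designs below the PSU, post-stratification or raking of weights,
seasonality and fasting-status effects (relevant to zinc), and non-lognormal
biomarker shapes. Results on real surveys depend on the pre-cleaning steps
the ingestion checks assume.

Problem sizes in the packaged tests and acceptance script were chosen to
make Monte-Carlo error small relative to the tolerances being checked:
200 replicates of n = 2000 for the prevalence-recovery comparison, 1000
replicates of a 480-row stratified-cluster design for interval coverage,
and n = 5000 single datasets for slope-removal checks.

# Known limitations

* Only the regression-correction adjustment is implemented — no
  correction-factor, exclusion or raised-cutoff methods.
* Variance estimation is Taylor linearization only: no replicate weights
  (BRR/jackknife), no finite-population corrections, no multi-stage
  nesting below the PSU.
* Zinc cutoffs vary with fasting status and time of day; the cutoff
  matcher keys only on group, sex and age, so such analyses require
  subsetting upstream and a modified cutoff table.
* The lowest-decile reference is dataset-internal by default; surveys with
  atypically inflamed populations may prefer externally supplied
  references, which the configuration accepts on the ln scale.
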