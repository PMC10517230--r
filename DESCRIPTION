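Package: mnsurvey
Title: Micronutrient Biomarker Survey Analysis with Inflammation Adjustment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Template-driven analysis of population micronutrient biomarker
    surveys. Ingests participant-level datasets in CSV, Excel, SAS, SPSS or
    Stata format, validates them against a dataset-descriptor template,
    standardizes variable names and converts concentrations to SI units,
    applies the BRINDA regression-correction inflammation adjustment (ln AGP
    and/or ln CRP with lowest-decile reference values) to ferritin, soluble
    transferrin receptor, retinol-binding protein, retinol and zinc, and
    produces design-based summary statistics (means, geometric means,
    quantiles) and deficiency-prevalence estimates with Taylor-linearized
    standard errors under stratified one-stage cluster sampling, classified
    against age-, sex- and population-group-specific cutoffs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    haven,
    readxl,
    stats,
    tools,
    utils,
    zip
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
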