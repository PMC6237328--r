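Package: chronicsim
Title: Synthetic Initial Populations for Chronic-Disease Micro-Simulation and
    Their Internal-Consistency Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs the joint age- and sex-specific distribution of a
    categorical risk factor and multiple chronic diseases from marginal
    prevalence data, under the assumption that prevalence odds ratios equal
    incidence rate ratios, and validates the construction by simulating a
    disease-free newborn cohort to demographic equilibrium under stationary
    risk-factor prevalence (net transition rates).  Includes a partial
    micro-simulation engine with exact within-year evolution by matrix
    exponentials of competing-risk generators, baseline-incidence calibration,
    comorbidity-ratio and within-disease risk-factor-distribution metrics,
    replicate-based confidence intervals, and a synthetic scenario generator
    emulating smoking-like and adiposity-like settings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
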