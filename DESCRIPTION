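Package: evocquant
Title: Quantitative Immunohistochemistry Morphometry and Viability Scoring
    for Tumor Ex Vivo Organ Cultures
Version: 0.1.0
Authors@R:
    person("EVOC", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for quantifying tumor viability in ex
    vivo organ culture (EVOC) experiments from brightfield
    immunohistochemistry (IHC) images. Implements H-DAB color deconvolution
    in optical-density space, watershed-based nucleus detection with size
    gating and DAB positivity calling, region-of-interest restricted
    morphometry (overall, tumor and stromal cell numbers and the Ki-67
    proliferation index), trapezoidal area-under-the-curve viability
    summaries with an EVOC score comparing culture arms, and the
    repeated-measures statistical battery used for longitudinal EVOC
    cohorts (Shapiro-Wilk screening, repeated-measures ANOVA with Mauchly,
    Greenhouse-Geisser and Huynh-Feldt sphericity handling, Tukey or
    Bonferroni post hoc contrasts with Cohen's dz, and Friedman sensitivity
    tests). A synthetic-data module renders ground-truthed H-DAB tiles by
    Beer-Lambert stain mixing and simulates longitudinal patient cohorts
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
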