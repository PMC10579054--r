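Package: hoquant
Title: Quantification of Heterotopic Ossification Lesions from NaF PET-CT and
    Crossover Trial Endpoint Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify heterotopic ossification (HO) lesions from
    co-registered 18F-NaF PET and CT volumes (standardized uptake value
    statistics, 40-percent-of-SUVmax metabolic-volume segmentation, total
    lesion activity), to apply trial-style lesion classification rules
    (active-lesion criterion, CT density and volume thresholds for new
    lesions, dual-reader adjudication), to derive patient-level endpoints
    (time-weighted average percent change with prespecified imputation,
    per-period new-lesion summaries), and to run the paired statistical
    layer of a placebo-to-treatment crossover design (exact Wilcoxon
    signed-rank, McNemar, relative risks, fixed-sequence gatekeeping,
    ANCOVA/MMRM/GEE-style model fits). A synthetic phantom and cohort
    generator makes the full pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    nlme,
    purrr,
    readr,
    rlang,
    RNifti,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
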