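Package: mrdflow
Title: Specimen Adequacy and Analytical Sensitivity for Multiple Myeloma
    MRD Testing by Next-Generation Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing bone-marrow specimen adequacy and the
    analytical performance of minimal-residual-disease (MRD) testing by
    next-generation flow cytometry in multiple myeloma. Implements
    blank-sample statistics (limit of blank, limit of detection, lower
    limit of quantification), revised detection limits for low-input
    specimens, hemodilution classification from mast-cell content,
    MRD status calls with disease-burden bands at configurable virtual
    sensitivities, a bootstrap root-mean-square-error scan that selects
    the achievable assay sensitivity, adequacy-qualified specimen
    reports, and a seeded synthetic-cohort generator that emulates the
    statistical structure of a clinical MRD specimen stream.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
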