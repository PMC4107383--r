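Package: netrecruit
Title: Task-Dependent Recruitment of Intrinsic Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies task-dependent recruitment of intrinsic (resting-state)
    brain networks from functional MRI. Projects 4-D BOLD series onto fixed
    network spatial maps to obtain component timecourses, screens ICA
    decompositions for slice-stripe motion artifacts, fits per-subject task
    GLMs with hemodynamic-response convolution, and relates recruitment betas
    to behavioural performance through stepwise covariate selection followed
    by Huber robust regression. A seeded synthetic-cohort generator with known
    ground truth makes every stage verifiable without real scans.
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
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    car,
    MASS,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
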