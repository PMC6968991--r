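Package: acidinvasion
Title: Two-Phenotype Acid-Mediated Tumour Invasion in One Dimension
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a one-dimensional five-field reaction-diffusion model
    of tumour invasion in which an acid-producing (glycolytic) phenotype and
    a matrix-degrading phenotype interact through Lotka-Volterra competition
    while invading stroma and extra-cellular matrix. Provides the
    non-dimensional model kinetics and parameter maps, a method-of-lines
    solver with density-dependent diffusion and stiff implicit (BDF) time
    stepping, closed-form enumeration and numerical linear-stability
    classification of the homogeneous steady states, invasion-front and
    tumour-mass metrics with dimensional unit conversion, and scripted
    drivers for single-population, competition-sweep, snapshot, perturbation
    and matrix-degradation sensitivity experiments.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
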