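Package: ovodyn
Title: Oocyte Recruitment Dynamics and Fecundity Type from Stereology and Wholemount Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies teleost fecundity type (determinate vs indeterminate) from
    ovarian histology and wholemount oocyte measurements. Implements stereological
    oocyte packing density (Delesse volume fractions on Weibel-grid counts, shape
    factors, volume-based diameters, shrinkage and specific-gravity corrections),
    rule-based spawning-stage classification from the oocyte ratio (ORC),
    gamma/Gaussian mixture estimation of the previtellogenic/developing diameter
    threshold, allometric condition and gonadosomatic indices, phase-specific
    relative fecundities, de novo oocyte influx and batch-number calculus, and a
    seeded synthetic-ovary generator with known ground truth for validating every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
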