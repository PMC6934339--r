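Package: resistform
Title: Geometric Resistance-Form Analysis of Tapered Crown Preparations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Trigonometric and computational-geometry tools for the resistance
    form of simulated fixed-restoration tooth preparations modelled as
    rectangular-based frustums. Computes exact per-wall and total surface
    areas of four-wall tapered preparations, the surface-area augmentation
    contributed by supplemental axial grooves cut with a tapered fissure bur,
    and the maximal axial-wall taper that still resists rotation of a cemented
    restoration about its cervical margin axis (the half-arcsine rule).
    Includes independent numeric oracles (surface triangulation and a 2-D
    arc-sweep interference test), a seeded synthetic parameter-grid generator,
    and a replication report that compares model output against bundled
    published reference tables.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
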