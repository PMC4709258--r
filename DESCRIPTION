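Package: clonedyn
Title: Progenitor Counting and Clonal Dynamics from Multicolor Lineage Tracing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of multicolor (confetti-style) lineage
    tracing of organ-founding progenitors. Implements the monoclonality
    filter for low-dose clonal induction, progenitor-number estimation from
    mean clone surface fractions and from cluster counts in mosaic-labeled
    organs, Monte Carlo quantification of clone merging by neighbor
    co-labeling on a triangular lattice, a Galton-Watson-with-immigration
    model of surface clone size with negative-binomial fitting and
    bimodality testing, and division-rate estimation from clone volumes and
    surface areas. Ships a synthetic cohort generator with the same
    statistical structure the estimators assume, so every stage of the
    pipeline is testable end to end without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
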