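Package: corescale
Title: Optimal Sampling Percentage for Plant Core Collections by Monte
    Carlo Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Determines the optimal sampling percentage of a plant
    (sub)core collection from quantitative-trait data. Subsets are
    constructed by least distance stepwise sampling (LDSS) under six
    genetic distances with UPGMA clustering, scored by seven evaluation
    statistics (MD, VD, CR, VR, CR_max, CR_min, CR_mea), and the validity
    of each statistic is assessed by Tukey homogeneous-population
    counting. A Monte Carlo simulation builds a coincidence-rate surface
    over sampling percentage and trait count, candidate formula families
    are fitted to the surface by nonlinear least squares, and the
    selected formula is inverted at a coincidence-rate threshold to give
    the optimal sampling percentage per number of traits. Includes a
    synthetic multi-environment field-trial generator and a fixed-effects
    least-squares genotypic-value adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
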