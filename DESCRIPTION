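Package: ibrtox
Title: Threshold-Based Integrative Biomarker Response Analysis for
    Ecotoxicology Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for multi-biomarker ecotoxicology studies built around
    the threshold-based Integrative Biomarker Response index (IBR-T):
    assay-unit derivations for enzyme activities and cell viability,
    tie-corrected Kruskal-Wallis and Dunn post hoc tests, non-metric
    multidimensional scaling with Kruskal stress-1, iterative low-rank
    imputation of missing biomarker values, and Type III factorial ANOVA
    under sum-to-zero contrasts. A seeded synthetic-study generator
    reproduces the statistical structure of a dose-by-time crustacean
    exposure design so every stage of the pipeline can be exercised and
    verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    vegan,
    jsonlite
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
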