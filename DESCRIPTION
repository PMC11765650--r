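Package: asymscreen
Title: Fluctuating-Asymmetry Screening of Craniofacial Inter-Foramina
    Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for screening mandibular condylar hyperplasia from
    bilateral craniofacial distance measurements between the supraorbital,
    infraorbital and mental foramina. Computes Palmer-style fluctuating
    asymmetry indices (FA1, the absolute right-left difference, and FA2,
    the same difference normalised by the bilateral mean) per paired trait
    and their composite sums, compares sexes and diagnostic groups with
    rank-based tests (Mann-Whitney, Kruskal-Wallis with
    Dwass-Steel-Critchlow-Fligner or Dunn post-hoc), and evaluates each
    index as a screening predictor via an exact empirical ROC engine with
    Youden-optimal cutpoints, sensitivity, specificity and predictive
    values. A calibrated synthetic-cohort generator reproduces the
    statistical structure of such studies so every pipeline stage is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
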