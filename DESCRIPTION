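Package: rhythmdesign
Title: Optimal Measurement Timing for Biological Rhythm Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing biological-rhythm discovery experiments with
    cosinor (harmonic regression) analysis. Computes the exact statistical
    power of the fixed-period cosinor F-test at arbitrary measurement times
    via the noncentral F distribution, scores designs by the worst-case
    (minimum over acrophase and frequency) power through a minimum-eigenvalue
    criterion on the trigonometric information matrix, and constructs optimal
    or near-optimal designs by exhaustive necklace search, eigenvector
    cutting-plane conic optimization, differential evolution, and constrained
    stochastic search. Also provides free-period permutation tests of
    rhythmicity (integrated- and peak-amplitude statistics), permutation-based
    power estimation, jitter-robustness analysis, and synthetic rhythmic
    signal generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
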