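Package: fdrscan
Title: Permutation-Based FDR Confidence Intervals Across Discovery
    Thresholds with Selection-Adjusted Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates the positive false discovery rate (pFDR) from
    permutation replicates for a nested series of candidate discovery
    thresholds, with delta-method confidence intervals on the log-FDR
    scale that account for the number of permutations and for
    over-dispersion of permutation rejection counts under dependence.
    Implements a false coverage-statement rate (FCR) procedure that uses
    one-sided Wald tests and Benjamini-Hochberg step-up selection to
    identify thresholds whose FDR intervals exclude one, widening the
    selected intervals so that post-selection coverage is retained.
    Includes a block-correlated Gaussian simulation engine with a true
    pFDR oracle for validating coverage of selected intervals, discovery
    plots over the threshold grid, and tabular readers and writers for
    p-value and rejection-count inputs.
License: MIT + file LICENSE
Encoding: UTF-8
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
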