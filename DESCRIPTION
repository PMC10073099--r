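Package: recabc
Title: Recursive Computed ABC Analysis for Minimal Informative Feature Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computed ABC (cABC) analysis partitions a vector of non-negative
    item values (feature importances, eigenvalues) into subsets "A", "B" and
    "C" using boundaries computed from the ABC (reversed Lorenz) curve: the
    Juran point closest to the ideal Pareto point (0, 1) marks the A|B limit
    and the break-even point where the curve slope equals 1 marks the B|C
    limit. Applied recursively to successive "A" subsets, with a
    Kolmogorov-Smirnov uniformity stopping rule, it shrinks a feature set to
    a minimal informative core. The package also provides a distribution
    simulation harness, principal-component retention by cABC analysis of
    eigenvalues with back-transformation, and a permutation-importance
    feature-selection pipeline with stratified holdout evaluation and a
    permuted-target control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
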