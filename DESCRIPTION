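Package: signalbias
Title: Sensitivity of Phylogenetic Signal Tests to Polytomies and
    Pseudo-Chronograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation toolkit for quantifying how unresolved phylogenies
    (polytomic chronograms) and interpolated branch lengths (BLADJ-style
    pseudo-chronograms) bias Blomberg's K and Pagel's lambda and their
    significance tests. Provides a pure-birth chronogram simulator, two
    node-collapsing degradation strategies, a time-sliced age-constraint
    selector with an even-interpolation calibrator, lambda-rescaled
    Brownian trait simulation, from-scratch implementations of Blomberg's
    K with a randomization test and Pagel's lambda with maximum-likelihood
    estimation and a likelihood-ratio test (both valid on polytomic
    trees), and a paired type-I/type-II bias analysis over the full
    factorial design, with tidy tabular outputs and ggplot2 graphics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
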