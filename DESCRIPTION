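Package: poolrna
Title: Design and Evaluation of RNA Sample Pooling Strategies for RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating RNA sample pooling strategies
    in bulk RNA-seq experiments. Implements a stochastic data-generating model
    for pooled libraries (random pool assignment, symmetric Dirichlet mixing
    weights, additive technical noise) with closed-form moments, analytic
    power of the two-sided negative binomial likelihood-ratio test under
    pooling, a linear cost model with power-versus-cost trade-off grids, a
    negative binomial count simulator with built-in differential-expression
    truth, an in-silico pooling and depth-thinning scenario engine, and a
    simulation-based evaluation pipeline that scores and ranks experimental
    designs by log-fold-change bias, signal-to-noise, concordance, false
    discovery rate and sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
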