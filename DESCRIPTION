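Package: nmphsim
Title: Simulating Representational Change with Nonmonotonic Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: A rate-coded neural network simulator for studying how
    competition between memories reshapes their neural representations.
    The network settles under tie-tolerant k-winners-take-all inhibition
    with sinusoidal inhibitory oscillations, and learns with an
    unsupervised, U-shaped (nonmonotonic) plasticity rule applied to
    unit coactivities at the end of every trial.  Builders are included
    for three simulated paradigms -- stimulus-similarity manipulation of
    color memories, shared versus different paired associates, and
    blocked versus interleaved curricula -- together with tidy analysis
    tools for within-pair pattern correlation, center-of-mass repulsion,
    run classification, and multidimensional-scaling visualization of
    representational change.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    readr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
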