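Package: emgknee
Title: EMG-Driven Knee Musculoskeletal Modelling, Identification and
    Sensitivity-Based Simplification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-muscle Hill-type musculoskeletal model of the knee joint
    driven by surface electromyography (biceps femoris, rectus femoris,
    vastus lateralis, vastus medialis), with real-coded genetic-algorithm
    identification of the 26 model parameters, variance-based (Sobol')
    global sensitivity analysis of the identified model, and a
    sensitivity-driven model-simplification procedure that fixes
    low-sensitivity parameters at population means and sweeps the number of
    identified parameters. Includes surface-EMG signal conditioning
    (band-pass, rectification, envelope, MVC normalization), a synthetic
    subject generator for end-to-end testing, and plotting and broom-style
    tidier methods for all result types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
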