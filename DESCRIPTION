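Package: oecspin
Title: Exchange-Coupled Spin Hamiltonians and Powder EPR Spectra for the
    Mn4CaO5 Cluster
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the S2-state Mn4CaO5 cluster of photosystem II
    as an exchange-coupled four-spin system. Extracts pairwise Heisenberg
    exchange couplings from broken-symmetry configuration energies by
    singular-value-decomposition least squares, diagonalizes the exchange,
    zero-field-splitting, and Zeeman Hamiltonians exactly in the full product
    space, labels the resulting spin ladder by total spin, and simulates
    field-swept powder-averaged X-band EPR absorption spectra from which
    effective g values are read off. Includes a synthetic generator for
    broken-symmetry energy tables and a catalogue of published coupling sets
    for the open- and closed-cubane S2 conformations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    tibble,
    tidyr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
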