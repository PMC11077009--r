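Package: stresschains
Title: Stress-Chain Percolation Analysis of Active Cell Monolayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-dimensional multi-phase-field model of confluent cell
    monolayers on a rigid substrate, with contact-inhibition-of-locomotion
    polarity dynamics and active traction forces, together with the analysis
    chain used to study the spatial organization of active stress chains:
    coarse-grained stress tensor fields on a complementary lattice,
    pair-correlation solid/liquid diagnostics, percentile-threshold site
    percolation of isotropic stress fields, and finite-size-scaling
    estimation of the percolation threshold and critical exponents
    (pc, beta, gamma, nu) with bootstrap uncertainties. Synthetic-field
    generators (i.i.d. uniform, spectrally correlated Gaussian, dipole
    stress chains, exact scaling-law curve sets) make every stage testable
    against the two-dimensional random-percolation universality class
    without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
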