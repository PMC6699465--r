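Package: protgamma
Title: Gamma Distances for Amino Acid Sequences Under Empirical
    Substitution Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates pairwise evolutionary distances between aligned
    amino acid sequences from uncorrected p-distances via the gamma
    distance d = a*b*((1 - p/b)^(-1/a) - 1), with Poisson-correction
    (b = 1) and equal-input (b = 1 - sum(pi^2)) variants.  Bundles
    published shape constants a for 27 empirical amino acid substitution
    models and re-derives them from first principles with a built-in
    calibration engine: continuous-time Markov chain sequence simulation
    along phylogenies, pairwise maximum-likelihood distance estimation,
    analytic divergence curves, and weighted Gauss-Newton nonlinear
    regression.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
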