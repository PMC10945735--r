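Package: vafdyn
Title: Stem Cell Dynamics from Variant Allele Frequency Spectra and
    Single-Cell Mutational Burdens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the accumulation of neutral somatic mutations in a
    stem cell population that grows from a single founder cell and is
    subsequently maintained by Moran-type symmetric divisions and
    asymmetric divisions.  Provides an exact stochastic (Gillespie)
    simulator of the three-phase demographic model at single-cell
    resolution, a method-of-lines solver for the expected variant allele
    frequency (VAF) spectrum under demographic change, closed-form
    spectra for the constant-size (Moran) and pure-birth limits, the
    hypergeometric sampling transform relating population and sample
    spectra, and estimators of the per-division mutation rate, the
    homeostatic division rate, the stem cell population size and the
    asymmetric-division fraction from single-cell mutational burden
    distributions and sampled VAF spectra.  Includes a synthetic-data
    generator emulating single-cell and bulk cohort study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
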