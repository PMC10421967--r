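Package: ncolen
Title: Length Distributions and Counts of Meiotic Non-Crossover Events
    from Gene Conversion Tracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers the length distribution and the genome-wide number of
    meiotic non-crossover (NCO) gene-conversion events from observed gene
    conversion tracts and the informative-marker maps of the transmitting
    parents.  NCO events are only detectable where they convert at least one
    heterozygous marker, so short events are systematically under-observed.
    The package models event lengths as a mixture of (shifted) negative
    binomial distributions, corrects for incomplete detection through exact
    detection and tract probability functions computed over all uniform
    placements of an event in the genome, and maximizes the resulting
    likelihood with an expectation-maximization algorithm.  It includes
    likelihood-ratio selection of the number of mixture components,
    inverse-detection estimation of the number of events per meiosis,
    bootstrap confidence intervals, and a simulator that generates marker
    maps and tract datasets with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
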