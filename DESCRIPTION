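Package: msciTools
Title: Simulation and Testing of Cross-Species Introgression Under the
    Multispecies Coalescent
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying gene flow between species under the
    multispecies coalescent with introgression (MSci).  Provides a species
    network representation with hybrid edges, a backward-time coalescent
    simulator of gene trees and Jukes-Cantor sequence alignments, quartet
    site-pattern counting with the HYDE estimator of the introgression
    probability and the ABBA-BABA D-statistic, a Savage-Dickey
    density-ratio Bayes factor engine for testing introgression from MCMC
    posterior samples, a fully analytic conjugate-normal testing example
    used to validate the Bayes-factor machinery, and an orchestration layer
    for power and false-positive simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
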