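Package: succinoflux
Title: Constraint-Based and Kinetic Analysis of Succinic Acid Overproduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for selecting an optimal malate dehydrogenase
    for succinic acid overproduction in a capnophilic rumen bacterium.
    Provides a stoichiometric model container with flux balance analysis
    (FBA), parsimonious FBA, flux variability analysis with a total-flux cap
    and cycle removal, FVSEOF amplification-target identification, flux-sum
    (metabolite turnover) analysis of cofactors under single and dual carbon
    sources, uncompetitive substrate-inhibition enzyme kinetics with
    nonlinear parameter estimation, and fermentation production indices
    (titer, glucose-equivalent yield, productivities). A synthetic-data
    module generates a reductive-TCA toy network, rate-law assay curves, and
    fermentation time series with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    minpack.lm,
    xml2,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
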