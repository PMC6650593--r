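Package: mran
Title: Microbial Recurrent Association Networks from Replicated Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers time-lagged local-similarity association networks from
    replicated OTU and environmental time series, merges edges that recur
    across sampling sites and depths into a consensus network, and
    characterises the result: small-world topology against Erdos-Renyi
    baselines, Louvain modules, within/among-module node roles (Zi-Pi),
    module monthly abundance patterns, cyanobacterial bloom-period
    labelling, and collapse of taxa into functional groups. Ships a
    synthetic multi-site compositional time-series generator with planted
    blooms, lagged couplings and modules so every stage is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
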