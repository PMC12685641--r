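Package: stingfoxo
Title: Kinetic Modeling and Network Analysis of cGAS-STING/IL-6/FOXO-Driven
    Autophagy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compartmental kinetic model of the cGAS-STING, interleukin-6 and
    FOXO1/FOXO3a signaling axes driving autophagy in non-small cell lung
    cancer, together with the downstream analysis stack: stiff deterministic
    simulation, forward local sensitivity analysis, principal-component
    ranking of sensitivity scores, per-reaction flux ranking, quasi-potential
    model reduction, pathway crosstalk scoring, and CytoHubba-style network
    centrality and hub-frequency analysis. Ships a curated 6-compartment,
    72-species, 83-reaction model of the pathway, an SBML Level 3 exchange
    layer, and seeded generators of synthetic reaction networks for
    property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
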