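Package: wspia
Title: Topology-Based Pathway Impact Analysis with Interaction-Strength Weights
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Signalling pathway impact analysis (SPIA) combining hypergeometric
    over-representation of differentially expressed genes with topology-driven
    perturbation propagation, plus two weighted variants in which each edge's
    contribution is scaled by the interaction intensity of the gene pair:
    Pearson correlation of expression (PSPIA) or mutual information of
    binarized expression (MSPIA). Includes a KGML (KEGG XML) and signed
    edge-list pathway parser, a Welch t-test differential-expression front
    end, a bootstrap null for the perturbation statistic, a seeded synthetic
    fixture generator for two-condition expression data with pathway-linked
    correlation structure, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    xml2
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
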