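Package: riqtl
Title: QTL Mapping and Candidate-Gene Triage for Recombinant Inbred Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Systems-genetics analysis of quantitative traits in biparental
    recombinant inbred (RI) mouse families such as the BXD panel. Provides
    heritability estimation from replicated strain data, rank-preserving
    winsorization of outlier strains, Haley-Knott interval mapping with
    permutation and bootstrap resampling, kinship-corrected linear mixed-model
    association with leave-one-chromosome-out (LOCO) kinship, cis-eQTL
    classification of expression microtraits, a seven-criterion positional
    candidate-gene triage cascade, hypergeometric Gene Ontology
    over-representation of correlate networks with terminal-branch selection,
    and cross-trait correlate comparison. Includes a synthetic RI-panel
    generator that emulates sib-mated RI genetics (map expansion R = 4r/(1+6r))
    with planted QTL, cis-eQTLs and trait-correlated expression modules, so the
    whole pipeline is testable without external downloads. Readers and writers
    for GeneNetwork-style .geno genotype files and tab-separated trait,
    expression and annotation tables are provided.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
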