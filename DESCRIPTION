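Package: straindyn
Title: Strain-Resolved Eco-Evolutionary Dynamics of Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resolving coexisting bacterial strains from
    metagenomic SNP allele-frequency trajectories in serially passaged
    microbial communities, and for asking whether ecological interactions
    act at the level of strains or species. Provides SNP quality and
    persistence filtering, dynamic-time-warping k-means clustering of
    allele-frequency trajectories into strain models, strain abundance
    estimation, correlation-based interaction statistics with gamma-sampling
    and permutation null models, genomic analyses of strain differentiation
    (SNP effect classification, pseudogene detection, pN/pS, categorical
    enrichment, divergence-time estimates), a synthetic-community generator
    for validation, and minimal consumer-resource models under serial
    dilution that discriminate strain-specific from species-specific
    resource competition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    deSolve,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
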