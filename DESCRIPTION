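Package: digiplast
Title: Phenotypic Plasticity of Self-Replicating Digital Organisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compact Avida-style digital-organism system and analysis
    pipeline for studying phenotypic plasticity. Genomes are circular
    programs over a 26-instruction alphabet executed on a virtual CPU;
    organisms self-replicate by copying their genome and compute Boolean
    logic operations on environment-supplied 32-bit numbers. The package
    traces transcriptomes (the instruction sequence actually executed
    during one gestation) across reproducible environments, classifies
    genomes as plastic/non-plastic and robust/sensitive, quantifies
    viability and generation-time costs, detects tandem repeats in
    execution traces, measures phenotypic uncertainty as Shannon entropy,
    and fits the associated generalized linear models, including a
    zero-truncated negative binomial regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    glmmTMB
Config/testthat/edition: 3
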