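Package: hybridase
Title: Allele-Specific Expression and Regulatory Divergence in F1 Hybrids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for dissecting cis- and trans-regulatory
    variation with RNA-seq of F1 hybrids between sequenced parental strains.
    Provides SNP-aware allele-specific read classification over paired
    orthologous open reading frames, TMM normalization with a conditional
    negative-binomial exact test for allele-specific expression (ASE),
    position-weight-matrix promoter scanning under the GOMER occupancy model
    to predict allele-specific transcription-factor binding (ASB),
    permutation-based association of ASB with ASE, a context-specific
    expression (CSE) statistic that detects strain differences in
    trans-activity from the shared hybrid nucleus, directional allelic
    selection sets with hypergeometric gene-set enrichment, and a seeded
    synthetic-data generator with full ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    fgsea,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
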