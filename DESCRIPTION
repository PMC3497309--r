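Package: ploidyDGE
Title: Two-Library Digital Gene Expression Analysis for Ploidy Comparison Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the statistical core of a
    diploid-versus-autotetraploid birch (Betula platyphylla) transcriptome
    analysis: Phred-based read filtering and library summary statistics,
    RPKM quantification, the Audic-Claverie exact two-library test for
    differential expression with Benjamini-Hochberg FDR and fold-change
    thresholds, hypergeometric GO/KEGG term enrichment with Bonferroni
    correction, 2^-ddCt relative qPCR quantification with dual reference
    genes, and per-family phenotype comparisons between ploidy groups.
    All pipeline inputs can be generated synthetically with known ground
    truth, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    Biostrings,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
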