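Package: mlmeqtl
Title: Mixed-Model eQTL Scanning with Leave-One-Chromosome-Out Genomic Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Transcriptome-wide expression quantitative trait locus (eQTL)
    analysis of GWAS signals under a single-variant mixed linear model with a
    polygenic random effect. Implements Hardy-Weinberg exact-test and minor
    allele frequency genotype filters, a GWAS-signal selection funnel,
    leave-one-chromosome-out genomic similarity matrices, AI-REML variance
    component estimation, fixed-effect tests via Henderson's mixed model
    equations, EM haplotype-frequency estimation with Gabriel-style D-prime
    confidence-interval linkage disequilibrium blocks, cis/trans
    classification, and a synthetic-data generator matching the model's
    generative assumptions for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
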