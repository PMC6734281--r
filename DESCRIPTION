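Package: enhloop
Title: Linking Non-Coding GWAS Variants to Target Genes via Enhancers,
    eQTLs and Chromatin Topology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative cascade for interpreting non-coding
    disease-associated variants. Filters GWAS catalog associations,
    classifies variants by genomic region, annotates them with
    chromatin-state enhancer calls across epigenomes, joins them to eQTL
    target genes with Storey q-value control, tests enrichment of eQTL
    genes among case/control differentially expressed genes with a
    hypergeometric fold-enrichment statistic, and interrogates chromatin
    topology from Hi-C-style read pairs: restriction-fragment assignment
    and filtering, iterative matrix balancing, maximum-likelihood TAD
    segmentation by dynamic programming, and 4C-style viewpoint
    interaction calling against a distance-decay background with FDR
    control. Ships a synthetic-data module that generates every input
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
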