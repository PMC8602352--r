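Package: promark
Title: Integration of Promoter Histone-Mark Dynamics with Differential
    Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline linking broad histone-mark ChIP-seq
    domains to transcriptome dynamics across developmental stages. Calls
    broad H3K27me3-style domains from IP/input fragment data with an
    island model (Poisson scoring, Benjamini-Hochberg q-values), quantifies
    promoter signal as IP/input RPKM ratios, classifies gene expression
    into quartile levels from TPM, tests differential expression with a
    moderated negative-binomial Wald test, and intersects promoter-mark
    changes with expression changes to extract genes whose promoter mark
    anti-correlates with their expression (HDEGs). Includes TSS metagene
    profiling stratified by expression class, over-representation and
    gene-set enrichment analysis, and a fully deterministic synthetic-data
    generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
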