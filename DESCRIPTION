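Package: exitkit
Title: Methylome, Motif, Expression and qPCR Analytics for
    Pluripotency-Exit Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analytical toolkit for temporal multi-omic studies of
    embryonic stem cell differentiation. Implements tile-based
    differential and temporal methylation calling from
    reduced-representation bisulfite sequencing (RRBS) coverage files,
    genomic-region methylation dynamics and gene-body metagene profiles,
    bipartite E-box motif scanning with exact enrichment tests in
    promoters of differentially expressed genes, ChIP peak proximity
    enrichment at demethylated regions against a permutation null,
    TPM-based gene filtering with pi-value ranking and DEG persistence,
    and quantile normalisation with limit-of-detection scoring for
    high-throughput RT-qPCR panels. Ships synthetic-data generators with
    exported ground truth so every stage is testable end to end without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    edgeR,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    methods,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
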