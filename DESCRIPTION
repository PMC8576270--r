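Package: inflammeth
Title: Paired Somatic Variant and Whole-Genome Bisulfite Methylome Analysis
    for Chronic Inflammation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for the joint genetic and epigenetic analysis
    of chronically inflamed tissue against matched controls. Implements
    paired mucosa/muscularis somatic variant accounting (mapping-quality and
    depth filters, exact-key germline subtraction, SNP/InDel counts and the
    allele-frequency SUM statistic, gene assignment and multi-sample
    intersection), whole-genome bisulfite methylome profiling (CpG/CHG/CHH
    context classification, binomial methylation calling, mC-type ratios,
    chromosome-level mC density, 9-bp sequence context matrices, metagene
    profiles), a six-criterion differentially methylated region (DMR) caller
    based on site chaining, fold change and Pearson's chi-square test, and
    DMR-to-gene zone assignment with hypergeometric pathway enrichment.
    Ships a seeded synthetic-data generator with planted ground truth so the
    whole pipeline is testable end to end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    rtracklayer,
    vcfR,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
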