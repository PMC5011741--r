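Package: coexPatterns
Title: Differential and Dose-Response Co-Expression of lncRNA-mRNA Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide lncRNA-mRNA co-expression analysis for two-group
    (tumor/normal) RNA-seq count data. Provides sample- and gene-level
    quality-control filters, negative-binomial differential expression with
    empirical-Bayes dispersion via edgeR, a batched pairwise regression scan
    of mRNA expression on lncRNA expression with a tissue-by-lncRNA
    interaction, classification of pairs into differential and dose-response
    co-expression patterns under Bonferroni control, downstream network
    summaries (cis/trans classification, hub degrees, risk-SNP
    co-localization, hypergeometric gene-set enrichment), and a seeded
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    edgeR,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
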