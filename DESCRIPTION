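Package: zedchrom
Title: H2A.Z Chromatin Profiling, Context-Resolved Methylomes, and
    Ecotype-Aware Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for plant chromatin genomics built around
    the histone variant H2A.Z and DNA methylation. Provides context-resolved
    (CG/CHG/CHH) bisulfite methylation metaplots aligned at gene ends, windowed
    differential-methylation testing with a pooled-count two-tailed Fisher
    exact test, H2A.Z ChAP-seq nucleosome-midpoint enrichment tracks (IP minus
    input) with TSS/gene-body scoring and a nine-cluster tercile partition, an
    allele-aware differential-expression procedure that partitions RNA-seq
    reads between two parental ecotypes via SNP scaffolds and smoothed read
    count contributions, downstream association statistics (Spearman
    correlation with permutation p-values, kernel density estimates, set
    overlap tests), and a fully seeded synthetic-data generator that plants
    known methylation differences, enrichment tiers, and fold changes so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
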