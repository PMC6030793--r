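Package: polyhybrid
Title: Duplicated-Gene Expression Analysis in Allodiploid and Allotriploid Hybrids
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing duplicated-gene expression in interspecific
    hybrid and polyploid transcriptomes from gene-level count matrices.
    Provides FPKM quantification with a coexpression filter, an exact
    negative-binomial two-group differential expression test with
    median-of-ratios normalization and moment-based dispersion estimation,
    classification of every coexpressed gene into twelve expression-level
    dominance and transgressive categories, in-silico mid-parent dosage
    comparisons for diploid and triploid hybrids, and a sequence module that
    identifies reciprocal-best-hit orthologs, concatenates trimmed collinear
    alleles into linked long sequences, and summarises pairwise identity,
    base composition and a neighbor-joining tree. A synthetic-data generator
    produces count matrices and divergent transcript sequences with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
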