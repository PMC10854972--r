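Package: evsmallrna
Title: Sequence-Level Small RNA Analysis of Plasma Extracellular Vesicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for plasma extracellular-vesicle (EV)
    small RNA-seq studied at single-sequence (isomiR) resolution. Covers
    adapter/4N trimming and exact-sequence collapsing into a biotype-annotated
    count matrix, median-of-ratios normalization, a negative-binomial Wald
    differential-expression test with Benjamini-Hochberg correction,
    coefficient-of-variation and detection-overlap comparisons between EV and
    EV-depleted plasma fractions, a repeated-random-split three-loop elastic-net
    classifier with projection of preclinical converter samples, a top-10-gene
    logistic-regression benchmark, per-gene time-to-conversion regression, and
    pathology-informed cohort curation. Includes a fully seeded synthetic
    cohort generator that emulates the data structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    glmnet,
    jsonlite,
    pROC,
    stats,
    utils,
    yaml
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
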