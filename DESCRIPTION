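Package: mirbundle
Title: UMI-Aware miRNA-Seq Quantification and Paired Muscle/EV Differential
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for small-RNA sequencing of engineered human
    skeletal muscle ("myobundles") and the extracellular vesicles (EVs) they
    secrete. Provides UMI-aware read-to-miR quantification from SAM alignments
    against miRBase-style GFF3 annotation (multimap filtering, seed-anchored
    coordinate matching with 3' tolerance, UMI deduplication), low-expressor
    filtering and normalization (TMM, median-of-ratios size factors, TPM),
    paired quasi-negative-binomial differential expression with subject
    blocking under a dual-normalization design, myobundle-EV Pearson
    correlation and preferential-expression detection, hypergeometric
    over-representation analysis, a normalization-method comparison, and a
    synthetic-data generator with planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    edgeR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
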