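Package: lumishift
Title: Luminal Lineage Biomarker Analysis for SERD Response in ER+ Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stratifying response to next-generation selective
    estrogen receptor degraders (SERDs) in ER+ breast cancer from bulk
    transcriptomic, immunohistochemistry, and chromatin profiling data.
    Implements reference-cohort z-scoring of gene signatures and
    Lum-high/Lum-low classification, Kaplan-Meier and log-rank survival
    stratification, variant-allele-fraction mutation inference from read
    pileups, IHC H-scores, paired differential expression, preranked gene-set
    enrichment, per-gene response association with covariates, transcription
    factor target enrichment, differential chromatin peak classification with
    motif enrichment and co-occurrence partitioning, peak-to-TSS proximity
    mapping, and expression trend tests. Ships synthetic-data generators that
    emulate every input with planted effects so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    fgsea,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
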