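Package: lifemeth
Title: Lifestyle-Index Epigenome-Wide Association and Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline linking a composite lifestyle index to
    DNA methylation and type 2 diabetes. Builds an unweighted 0-8
    comprehensive lifestyle index (CLI) from smoking status, alcohol intake,
    physical activity and diet quality; detects CLI-associated
    differentially methylated positions on Illumina-450k-style beta values
    (per-probe least squares on M-values, empirical-Bayes variance
    moderation, empirical-null bias/inflation correction and
    Benjamini-Hochberg FDR); detects differentially methylated regions by
    bump hunting with permutation familywise error rates; associates top
    probes with T2DM, fasting glucose and HbA1c; and quantifies mediation of
    the lifestyle-T2DM association through methylation with bootstrap
    confidence intervals. Ships a synthetic-data generator with known ground
    truth so the whole chain is testable without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite
Suggests:
    limma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
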