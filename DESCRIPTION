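Package: dreamdrift
Title: Restriction-Signature DNA Methylation Quantification and
    Age-Related Drift Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies CpG methylation from DREAM (Digital Restriction
    Enzyme Analysis of Methylation) sequencing counts at CCCGGG sites,
    with spike-in based correction-factor calibration, depth and
    autosome filtering, and CpG-island/shore/promoter annotation.
    Provides pairwise differential methylation (volcano calls at a
    joint p-value and 5 percentage-point magnitude rule), a per-site
    multivariate linear model attributing methylation to microbiota,
    Il10 deficiency and azoxymethane exposure with Benjamini-Hochberg
    FDR, set-overlap (UpSet) pattern counts, age-related methylation
    drift concordance statistics and promoter-level cancer enrichment
    odds ratios. A synthetic-data module generates complete study
    inputs with known ground truth so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: DNAMethylation, Epigenetics, Sequencing, DifferentialMethylation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
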