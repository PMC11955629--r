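Package: mockbench
Title: Mock-Community Accuracy and Replicate Reproducibility for
    Species-Level 16S Amplicon Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Benchmarking toolkit for species-level 16S rRNA amplicon
    profiles evaluated against defined mock communities. Provides a
    SummarizedExperiment-based container for taxa-by-sample abundance
    tables with lineage annotations; plate-wise contaminant filtering
    against negative controls and median library-size normalisation;
    confusion-based performance scoring (precision, sensitivity,
    F-score), observed/expected abundance ratios and
    percent-correctly-classified summaries against a mock reference
    such as the 8-species ZymoBIOMICS standard; alpha diversity
    (observed richness, Shannon, Simpson) and beta diversity
    (Bray-Curtis, Jaccard); paired Wilcoxon tests and distance-based
    intraclass correlation coefficients (dICC) for technical-replicate
    and stool/swab pair designs; and a seeded synthetic-data generator
    emulating mock controls, plates with planted contaminants, and
    replicate pairs with known reproducibility.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
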