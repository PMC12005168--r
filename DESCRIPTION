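Package: agetraj
Title: Trajectory-Based Differential Expression for Aging Time-Course RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for lifespan-scale, multitimepoint bulk RNA-seq
    of an aging cohort. Provides a seeded synthetic-data generator emulating a
    survivorship-indexed sampling design (Gompertz mortality, negative-binomial
    counts with per-gene expression trajectories), a self-contained
    negative-binomial GLM differential-expression engine running three designs
    (chronological age, cohort mortality fraction, and a categorical
    sampling-point likelihood-ratio test), Z-score expression-trajectory
    hierarchical clustering with Pearson dissimilarity, Bonferroni-rule
    classification of cluster trajectories as LinearUp, LinearDown or Complex,
    a two-timepoint young-versus-old reanalysis with sliding old windows and
    trajectory-class concordance, and cluster-wise hypergeometric gene-set
    over-representation against a custom expressed-gene background.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    splines,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
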