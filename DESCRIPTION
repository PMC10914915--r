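Package: glaiQTL
Title: Genetic Dissection of Green Leaf Area Index Dynamics in a Maize
    MAGIC Panel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to characterise maize green leaf area index (GLAI)
    dynamics and map their genetic determinants in a multi-parent
    (MAGIC) doubled-haploid panel. Plot-level GLAI time series on a
    thermal-time (GDD6) axis are segmented into five developmental
    phases with two bent-cable regressions, from which 24 slope,
    duration and area-under-the-curve traits are derived. Genotype
    adjusted means are estimated with spatially autocorrelated
    field-trial models, generalized (Cullis) heritability and
    multi-environment variance components are computed, and traits are
    mapped with univariate and multivariate linear mixed-model GWAS
    using leave-one-chromosome-out identity-by-state kinships and
    Storey q-values. Significant SNPs are clustered by linkage
    disequilibrium, promoted to QTLs by multi-environment backward
    elimination, tested for colocalization, and used to quantify the
    grain-yield variance explained by GLAI QTLs across a drought
    network. A synthetic MAGIC-panel generator with a recorded ground
    truth supports recovery testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
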