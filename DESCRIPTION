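Package: consensusRFE
Title: Consensus SVM-RFE Feature Selection for Paired Blood-Chemistry Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies blood-chemistry measures that shift consistently
    between paired pre- and post-exposure samples by recursive feature
    elimination on kernel support vector machines, aggregated across
    hundreds of resampled train/test partitions by majority-rule voting.
    Includes a synthetic paired-cohort simulator driven by per-analyte
    Gaussian parameters, nested feature-combination accuracy curves for
    choosing the final consensus panel, and a paired t-test screen as the
    univariate baseline, together with top-k ranking overlap between the
    two selection routes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr
biocViews: Classification, FeatureExtraction, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
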