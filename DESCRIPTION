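Package: ulheart
Title: Cell-State Matching and Proliferation Statistics for Tunicate Heart Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for studying post-larval heart growth in the
    tunicate Ciona robusta from single-cell transcriptomes and EdU labeling
    experiments. Implements a single-cell preprocessing and Louvain clustering
    ladder (QC filtering, library-size normalization, covariate regression,
    scaling with clipping, highly-variable-gene selection, truncated PCA,
    knee-based component selection, sub-clustering on a preserved embedding);
    cross-dataset contaminant-cluster elimination by Pearson correlation of
    cluster centroids with replicate-calibrated thresholds, a near-threshold
    review band and an abundance-ratio veto; one-vs-rest Wilcoxon marker
    ranking and panel z-score matrices; EdU pulse/chase proliferation indices
    and a division-rate estimator with zero exclusion; a statistical ladder of
    normality-gated two-group tests, Fisher's exact test, paired t tests and a
    trial-stratified permutation test on exceedance proportions; and CRISPR
    amplicon indel classification relative to the PAM. Seeded synthetic-data
    generators emulate every input so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    irlba,
    FNN,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    yaml,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
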