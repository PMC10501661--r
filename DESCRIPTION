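Package: ranksim
Title: Reference-Based Normalization of Microbiome Counts via Rank Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Scaling normalization for sparse microbiome count tables that
    estimates per-sample sampling fractions from a data-driven reference set of
    non-differentially-abundant taxa.  Each taxon is scored by the median of its
    pairwise Spearman rank correlations with all taxa; an empirical-Bayes
    procedure with a resampled null distribution then thresholds these scores so
    that the misclassification rate of the selected reference set is controlled
    at a user-chosen level.  Ships self-contained baseline normalizers (total-sum,
    upper-quartile, median-of-ratios, trimmed mean of M-values, geometric mean of
    pairwise ratios, rarefaction), a multinomial simulator with planted ground
    truth, and an evaluation suite (misclassification rate, per-taxon tests with
    false-discovery bookkeeping, PERMANOVA, principal-coordinates analysis).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
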