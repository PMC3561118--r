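Package: hifdep
Title: Factor-Dependency Classification of Hypoxia-Responsive Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting which transcription factors a hypoxic
    transcriptional response depends on, using factorial genotype-by-oxygen
    expression designs. Implements SAM-style permutation differential
    expression (regularized d-statistic, data-driven fudge factor,
    exhaustive or sampled permutation q-values) with fold-change and FDR
    gating; dual-evidence set-logic schemes that classify hypoxia-responsive
    transcripts as HIF-dependent, HIF-independent, ERR-dependent or
    double-mutant-dependent; Venn partitioning and cumulative hypergeometric
    overlap and term-enrichment tests; metabolomics below-detection
    imputation, protein normalization and per-compound ANOVA with contrasts;
    delta-Ct relative qPCR quantification; and a synthetic-data generator
    with planted dependency classes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
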