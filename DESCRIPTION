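Package: motifsyntax
Title: Inference of Transcription Factor Motif Syntax from Sequence-to-Accessibility Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the regulatory syntax of transcription factor
    binding motifs with sequence-to-accessibility predictors. Implements in
    silico marginalization of motif pairs across all spacings and orientations
    to detect synergy and classify hard (fixed-arrangement) versus soft
    (distance-flexible) syntax, contribution-weight-matrix processing and
    contribution-aware motif instance calling with quality filtering and
    deduplication, genomic annotation of instances, motif co-occurrence tests,
    Tn5 insertion offset correction and footprint metaplots, in silico motif
    ablation, variant effect scoring, and permutation-based enrichment of
    fine-mapped eQTL variants in motif instances. A seeded synthetic
    accessibility predictor with planted motif effects and interactions stands
    in for trained deep models so every procedure can be exercised and
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    patchwork
Config/testthat/edition: 3
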