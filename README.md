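# motifsyntax

Tools for dissecting the **regulatory syntax of transcription factor
motifs** with sequence-to-accessibility predictors. Regulatory elements are
combinations of motifs, and some combinations act synergistically; when
they do, the cooperation may demand a fixed spacing and orientation of the
two binding sites (**hard syntax**) or only a flexible distance preference
(**soft syntax**). `motifsyntax` infers which, by *in silico
marginalization*: substituting motif consensus sequences into background
DNA at every arrangement and measuring what a predictive model of chromatin
accessibility makes of the edit.

For motifs A and B inserted into background sequences, with predicted
natural-log counts `y0` (background), `yA`, `yB` (single insertions) and
`yJ` (joint insertion at a given orientation and gap), the package computes

```
dA = yA - y0,  dB = yB - y0,  dJ = yJ - y0,  dS = dA + dB
```

and calls a pair **synergistic** when `dJ - dS` at the pair's optimal
arrangement is significantly positive (one-sided Wilcoxon signed-rank,
Benjamini-Hochberg adjusted p < 0.001) with a mean excess above 0.15 log
counts. Hard syntax: some arrangement's mean `dJ` exceeds the
across-arrangement mean by more than 4 standard deviations. Soft syntax:
`dJ - dS > 0.15` at some gap between 20 and 150 bp.

Around this core the package implements contribution-weight-matrix
processing (trimming at 30% of peak contribution, consensus extraction,
PPM/PFM conversion, similarity), a contribution-aware greedy motif instance
caller with the published quality filter (instance-CWM correlation >= 0.9)
and >3-bp overlap deduplication, genomic annotation
(promoter/exonic/intronic/distal, distance binning), motif co-occurrence
tests, Tn5 insertion offset correction (+4/-4 vs the legacy +4/-5) with
footprint metaplots, in silico motif ablation, variant-effect scoring, and
permutation-based enrichment of fine-mapped eQTL variants in motif
instances.

Because trained deep models and the underlying atlas data are not
redistributable at this scale, the package ships a **seeded synthetic
accessibility predictor** (`planted_model()`) that satisfies the same
contract with planted motif effects and hard/soft interactions, so every
procedure is validated end to end against exact ground truth. Any object
implementing `predict_log_counts()` / `predict_profile()` /
`contribution_scores()` can be substituted for it.

## Worked example

Plant a hard interaction (magnitude 0.4 log counts at orientation `A+B-`,
gap 20 bp) between two motifs with marginal effects 0.5 and 0.7, scan all
arrangements, and classify:

```r
library(motifsyntax)

model <- planted_model(
  c(GATAAGAT = 0.5, TTGACCAA = 0.7),
  interactions = interaction_rule("m1", "m2", "hard", magnitude = 0.4,
                                  orientation = "A+B-", gap = 20L),
  fold_jitter_sd = 0.05)
lib <- make_background_library(forbidden = c("GATAAGAT", "TTGACCAA"),
                               seed = 1)
et <- marginalize_pair(model, lib, "GATAAGAT", "TTGACCAA",
                       gaps = seq(0, 200, 10))
glance(et)
#> # A tibble: 1 × 7
#>   n_arrangements n_sequences n_folds opt_orientation opt_gap opt_mean_dJ ...
#> 1             84         100       5 A+B-                 20        1.60

classify_composite(et) |>
  tidy() |>
  dplyr::select(orientation, gap, mean_diff, p_adj, z_max, synergistic, syntax)
#> # A tibble: 1 × 7
#>   orientation   gap mean_diff    p_adj z_max synergistic syntax
#> 1 A+B-           20     0.397 6.34e-84  9.04 TRUE        hard
```

The screen recovers the planted optimum exactly: the best arrangement is
`A+B-` at gap 20 with mean `dJ - dS` of 0.397 (planted magnitude 0.4,
jitter sd 0.05), a vanishing adjusted p-value, and an arrangement z-score
of 9.0 -- far above the hard-syntax threshold of 4, so the pair is
classified `hard`. `autoplot(et)` draws the synergy landscape over gap and
orientation; `simulate_syntax_battery()` / `screen_syntax_battery()` run
the same pipeline over batteries of planted hard/soft/null pairs.

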