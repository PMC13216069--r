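---
title: "Inferring motif syntax with in silico marginalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring motif syntax with in silico marginalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifsyntax)
library(dplyr)
```

## The problem

Transcription factors do not act on isolated binding sites: chromatin
accessibility at a regulatory element reflects combinations of motifs, and
some combinations act synergistically -- the element is more accessible with
both motifs present than the two motifs' individual effects would predict.
When synergy exists it may be *hard*, requiring one precise spacing and
relative orientation of the two sites (the signature of a composite element
bound by a physically interacting pair), or *soft*, a flexible preference
for co-occurrence within tens to a hundred or so base pairs.

Sequence-to-accessibility models (convolutional networks trained to predict
ATAC-seq coverage from local DNA sequence) make this question answerable in
silico. `motifsyntax` implements the analysis layer on top of any such
predictor: in silico marginalization of motif pairs, statistical synergy
calling and hard/soft classification, motif-matrix processing and
contribution-aware instance calling, genomic annotation, Tn5-aware
footprinting, in silico ablation, variant-effect scoring, and permutation
enrichment of fine-mapped eQTL variants in motif instances.

## The marginalization model

For motifs A and B and a library of non-accessible background sequences, we
substitute the motif consensus sequences into each background and predict
natural-log total counts with every model fold:

* $y_0$ -- the unedited background;
* $y_A$, $y_B$ -- one motif substituted at the window center;
* $y_J$ -- both motifs substituted at a given *arrangement*.

The marginal effects are $\Delta_A = y_A - y_0$ and $\Delta_B = y_B - y_0$;
the joint effect is $\Delta_J = y_J - y_0$; and the log-additive
(independent) expectation is $\Delta_S = \Delta_A + \Delta_B$, a
multiplicative null on the count scale. Synergy is a significant excess of
$\Delta_J$ over $\Delta_S$.

An arrangement is a relative orientation plus an edge-to-edge gap. Modulo
reverse complementation of the whole insert there are 3 unique orientations
for a pair of identical motifs (tandem, head-to-head, tail-to-tail) and 4
for a distinct pair (`A+B+`, `A+B-`, `A-B+`, `A-B-`). Gaps are scanned from
0 to 200 bp.

Two conventions in this scan were genuinely open and are fixed as follows:

* **Distance is the edge-to-edge gap**, with the center-to-center distance
  reported alongside; the gap is what sequence editing directly controls.
* **Gap bases retain the background sequence** rather than being
  randomized, so the joint insertion differs from the two single insertions
  only by the presence of the second motif.
* The pair is centered as a whole about the window center, keeping both
  motifs maximally inside the profile window at every gap up to 200 bp.

## Synergy calling and syntax classification

Per composite, the *optimal arrangement* maximizes the mean $\Delta_J$ over
sequences and folds (ties: smallest gap, then canonical orientation order).
At that arrangement the paired differences $\Delta_J - \Delta_S$ per
(sequence, fold) are tested with a one-sided Wilcoxon signed-rank test;
p-values are Benjamini-Hochberg adjusted across the batch of composites
screened together. A composite is **synergistic** when the adjusted p-value
is below 0.001 *and* the mean difference exceeds 0.15 natural-log counts.

Syntax is classified among synergistic composites:

* **hard** -- some arrangement's mean $\Delta_J$ lies more than 4 standard
  deviations above the mean across all arrangements (z-score across
  arrangements, the optimum included);
* **soft** -- the mean $\Delta_J - \Delta_S$ exceeds 0.15 at some
  arrangement whose gap falls between 20 and 150 bp (measured edge to
  edge -- the configurable choice adopted here);
* a composite meeting both definitions is grouped as hard.

The signed-rank test enumerates its null exactly for up to 25 nonzero
differences -- including tied magnitudes, via a convolution over doubled
ranks -- and switches to a normal approximation with tie and continuity
corrections beyond that; the reported p is $P(W \ge W_{obs})$ under random
sign assignment. Zero differences are dropped before ranking, the standard
treatment.

An *interpretation guard* protects against edits whose predicted effect is
driven by sequence other than the inserted motifs: the fraction of total
absolute contribution mass falling inside the inserted-position mask must
reach 0.5 (configurable), otherwise the composite is reported with status
"abstained" and no classes.

## The synthetic predictor and what it does (not) emulate

No trained network ships with this package. Instead `planted_model()`
implements the same contract -- `predict(sequence, fold)` returning log
total counts and a per-base profile, with per-base (and hypothetical)
contribution scores -- using planted ground truth:

* each declared consensus adds its signed effect per exact match (both
  strands; palindromes counted once);
* a hard interaction rule adds its magnitude only at one (orientation,
  gap); a soft rule adds `magnitude * exp(-gap / decay_bp)` at any
  orientation, with `decay_bp = 40` so the planted preference is
  informative across the 20-150 bp soft range yet near-independent beyond
  about 100 bp;
* per-(sequence, fold) Gaussian jitter emulates variability across model
  folds. The jitter is a deterministic hash of (sequence content, fold,
  model seed), so the predictor remains a pure function as the contract
  requires while distinct edited sequences receive independent noise.

This emulation validates the *machinery* -- arrangement enumeration, effect
accounting, test calibration, classification thresholds, instance
post-processing -- against exact ground truth. It deliberately does not
emulate what makes real models hard: smooth partial-match effects, motif
affinity gradients, receptive-field edge artifacts, GC and Tn5 bias, or
epistasis beyond pairwise rules. A passing battery therefore demonstrates
correctness of the analysis layer, not performance of any trained model.

Background libraries are drawn by seeded rejection sampling to match a
target GC fraction (default 0.5 within 0.02) while excluding every planted
consensus and its reverse complement, so background predictions carry no
motif terms.

The syntax battery (`simulate_syntax_battery()` /
`screen_syntax_battery()`) plants hard, soft and null pairs with marginal
effects 0.3-0.8, interaction magnitudes 0.3-0.5 and fold jitter 0.05 over
100 backgrounds and 5 folds, and scans gaps 0-200 in 10-bp steps -- a grid
coarse enough to keep a 60-pair screen in a few minutes of CPU time while
leaving every planted hard gap on the grid. Candidate consensus pairs are
screened on probe backgrounds so that no arrangement creates a spurious
junction match, which would otherwise contaminate the arrangement spectrum.

## Instance calling and post-processing

The published pipeline identifies predictive motif instances with a sparse
linear reconstruction of contribution scores. The optimizer itself is not
part of this package's contribution; `greedy_hit_caller()` implements a
greedy matching-pursuit approximation -- repeatedly selecting the (motif,
offset, strand) with the highest Pearson correlation between the residual
contribution track and the CWM, recording `hit_correlation`, and
subtracting the least-squares-scaled CWM -- which is verifiable against a
brute-force scan on small tracks. The published post-hoc filters are
implemented exactly:

* **quality filter**: a motif is dropped, with all its instances, when the
  correlation between its input CWM and the mean contribution matrix over
  its instances falls below 0.9;
* **deduplication**: same-label instances overlapping by more than 3 bp
  keep only the highest `hit_correlation` (ties: leftmost, then first in
  input);
* **annotation**: promoter (within 2 kb of a TSS) > exonic > intronic >
  distal, evaluated at the instance center -- the paper lists the
  categories in this order without stating precedence, and center
  evaluation makes the precedence unambiguous;
* **distance binning**: 10-bp half-open bins from 0 to 250 bp from the
  nucleosome dyad or peak summit, z-scored across bins per motif (a
  constant positive profile has z = 0; a motif with no in-range instances
  has undefined z).

CWM trimming removes flanking positions whose total absolute contribution
falls below 30% of the maximum; the retained span is contiguous (an
interior sub-threshold column is kept), matching standard seqlet-trimming
practice, and absolute values make the same rule work for negative motifs.
Consensus bases maximize the contribution (absolute contribution for
negative motifs), with ties broken deterministically by base order A < C <
G < T.

## Footprinting and the Tn5 offset

Tn5 transposition duplicates 9 bp: one event at center $c$ reports a
plus-strand insertion at $c-4$ and a minus-strand insertion at $c+4$
(0-based first duplicated base per strand). Under the standard end-exclusive
fragment convention, adjusting fragment starts by +4 and (end - 1) by -4
maps both mates of a shared event to the same consensus coordinate, while
the legacy +4/-5 scheme leaves a 1-bp mismatch -- the package's simulator
and `tn5_mate_consistency()` reproduce both facts exactly, per event. The
exact coordinate bookkeeping behind the legacy discrepancy is a modeling
choice documented here: the convention was fixed so that the +4/-4 scheme
is self-consistent, which is the property the correction exists to provide.

Footprint metaplots sum insertion counts over 500-bp windows centered at
instances and divide by the mean count over the outer 10% of positions on
each side -- the local background accessibility.

## eQTL enrichment

Fine-mapped variant-gene pairs (deduplicated by keeping the higher
posterior inclusion probability) are intersected with deduplicated motif
instances under half-open coordinates. Allelic fold changes are permuted
across variants (100,000 shuffles by default), reassigning each variant's
direction; the enrichment score is the observed count over the mean
shuffled count, and significance requires BH FDR < 0.05 *and* an observed
count above the empirical 95% interval (2.5/97.5 percentiles -- the CI
construction was unspecified and percentiles are assumption-free) of
shuffled counts. A two-sided Fisher exact test compares, per motif
polarity, the numbers of motifs significantly enriched for upregulating
versus downregulating variants, reporting infinite odds ratios where a
zero cell forces them.

One deliberate deviation: the empirical p counts shuffles whose count
*reaches or exceeds* the observed one. Counting only strictly larger
shuffles is anticonservative on discrete counts (a motif overlapped by a
single variant would earn p near 1/n_shuffles under the null whenever that
variant's direction matches) and breaks super-uniformity of null p-values,
which the test suite verifies. A +1 pseudo-count keeps sampled p-values
positive; the exhaustive small-n mode reports the plain proportion.

## Variant effect scoring

For a variant inside the central profile window, both alleles are predicted
per fold; the package reports the sum of per-base predicted count
differences in the 100-bp window centered at the variant (truncated at
profile boundaries) and the log2 fold change of total predicted counts,
averaged across folds. With a planted effect of $e$ natural-log counts the
log2 fold change is $e \log_2 e$, a unit conversion the tests verify.

## In silico ablation

Instances are split into `hit_correlation` quartiles and 250 are sampled
per quartile (all, with a warning, when fewer exist). Each instance span is
replaced base by base with the base of smallest absolute hypothetical
contribution -- the most neutral base -- and the change in predicted log
counts, averaged over folds, is reported. On the planted oracle, ablating
an instance with effect $e$ yields $-e$ exactly.

## Numerical and problem-size choices

* Exact signed-rank enumeration up to n = 25 nonzero differences; normal
  approximation with tie/continuity corrections beyond.
* Similarity alignments require at least 50% column overlap of the shorter
  matrix, preventing spurious single-column correlations; zero-variance
  matrices are flagged degenerate with similarity 0.
* The validation battery uses 60 pairs (20 hard / 20 soft / 20 null), 100
  backgrounds, 5 folds and a 10-bp gap grid; the null-calibration run uses
  50 additive pairs. These sizes make the full suite run in minutes on one
  CPU while leaving the statistical margins wide (the hard-spike z exceeds
  9, the soft-kernel z stays near 3 against the threshold of 4).
* All genomic coordinates are 0-based half-open throughout, including
  insertion coordinates.

## Known limitations

* The planted predictor scores exact consensus matches only; affinity
  gradients and partial sites are out of scope by design.
* The greedy hit caller approximates, not reproduces, the sparse-regression
  instance caller; its competitive behaviour under heavily overlapping
  motifs will differ.
* Orientation codes for distinct pairs are defined relative to the
  argument order of `marginalize_pair()`; swapping arguments relabels the
  classes (the effects themselves are invariant, which the tests check).
* Enrichment counts each variant once per motif regardless of how many
  instances of that motif it overlaps.

## A minimal worked example

```{r example, eval = FALSE}
model <- planted_model(
  c(GATAAGAT = 0.5, TTGACCAA = 0.7),
  interactions = interaction_rule("m1", "m2", "hard", magnitude = 0.4,
                                  orientation = "A+B-", gap = 20L),
  fold_jitter_sd = 0.05)
lib <- make_background_library(forbidden = c("GATAAGAT", "TTGACCAA"),
                               seed = 1)
et <- marginalize_pair(model, lib, "GATAAGAT", "TTGACCAA",
                       gaps = seq(0, 200, 10))
classify_composite(et)
autoplot(et)
```
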