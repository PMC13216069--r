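# A seeded battery of motif pairs with planted syntax -- hard (single
# arrangement), soft (smooth distance kernel) or null (purely additive) --
# used to validate the whole marginalization-plus-classification pipeline
# against known ground truth.

# Random consensus pair screened so that, for every scanned arrangement, the
# edited insert produces exactly one match of each motif and no spurious
# junction match (verified on probe backgrounds).
.draw_screened_pair <- function(motif_length, gap_grid, window_length,
                                probes = 2L) {
  count_both <- function(seqs, pat) {
    pats <- unique(c(pat, .rc_string(pat)))
    dss <- Biostrings::DNAStringSet(seqs)
    sum(vapply(pats, function(p) {
      sum(Biostrings::vcountPattern(p, dss))
    }, numeric(1)))
  }
  repeat {
    a <- .random_dna(1L, motif_length, 0.5)
    b <- .random_dna(1L, motif_length, 0.5)
    if (identical(a, b) || identical(a, .rc_string(b))) next
    bg <- .random_dna(probes, window_length, 0.5)
    if (count_both(bg, a) > 0 || count_both(bg, b) > 0) next
    ok <- TRUE
    for (code in .DISTINCT_CODES) {
      for (gap in gap_grid) {
        ed <- build_edited_sequence(bg, a, b, orientation = code, gap = gap)
        if (count_both(ed, a) != probes || count_both(ed, b) != probes) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    if (!ok) next
    ed_a <- build_edited_sequence(bg, a)
    ed_b <- build_edited_sequence(bg, b)
    if (count_both(ed_a, a) != probes || count_both(ed_b, b) != probes) next
    return(c(a, b))
  }
}

#' Plant one motif pair with known syntax
#'
#' Builds a [planted_model()] for a random (screened) pair of distinct
#' consensus sequences with positive marginal effects and, depending on
#' `kind`, a hard interaction at one random (orientation, gap) arrangement,
#' a soft distance-decaying interaction, or no interaction at all.
#'
#' @param kind `"hard"`, `"soft"` or `"null"`.
#' @param seed Integer seed.
#' @param motif_length Consensus length in bp.
#' @param gap_grid Gaps that will be scanned (hard gaps are planted on this
#'   grid).
#' @param effect_range Range of marginal effects (natural-log counts).
#' @param magnitude_range Range of interaction magnitudes.
#' @param fold_jitter_sd Per-fold jitter standard deviation.
#' @param n_folds,window_length,baseline,decay_bp Passed to the model.
#' @return A list: `seq_a`, `seq_b`, `kind`, `orientation`, `gap`,
#'   `magnitude`, `effects`, `model`.
#' @export
plant_syntax_pair <- function(kind = c("hard", "soft", "null"), seed = 1L,
                              motif_length = 8L, gap_grid = seq(0L, 200L, 10L),
                              effect_range = c(0.3, 0.8),
                              magnitude_range = c(0.3, 0.5),
                              fold_jitter_sd = 0.05, n_folds = 5L,
                              window_length = 2114L, baseline = 2,
                              decay_bp = 40) {
  kind <- match.arg(kind)
  with_seed(seed, {
    pair <- .draw_screened_pair(motif_length, gap_grid, window_length)
    effects <- runif(2L, effect_range[1], effect_range[2])
    motifs <- tibble(label = c("A", "B"), consensus = pair, effect = effects)
    magnitude <- runif(1L, magnitude_range[1], magnitude_range[2])
    orientation <- NA_character_; gap <- NA_integer_
    rules <- switch(kind,
      hard = {
        orientation <- sample(.DISTINCT_CODES, 1L)
        gap <- sample(gap_grid, 1L)
        interaction_rule("A", "B", "hard", magnitude = magnitude,
                         orientation = orientation, gap = gap)
      },
      soft = interaction_rule("A", "B", "soft", magnitude = magnitude,
                              decay_bp = decay_bp),
      null = NULL
    )
    if (kind == "null") magnitude <- NA_real_
    model <- planted_model(
      motifs, interactions = rules, baseline = baseline,
      fold_jitter_sd = fold_jitter_sd, n_folds = n_folds,
      window_length = window_length,
      profile_length = min(1000L, window_length), seed = seed
    )
    list(seq_a = pair[1], seq_b = pair[2], kind = kind,
         orientation = orientation, gap = gap, magnitude = magnitude,
         effects = effects, model = model)
  })
}

#' Simulate a battery of syntax pairs
#'
#' @param n_hard,n_soft,n_null Number of pairs of each planted class.
#' @param seed Integer seed (per-pair seeds are derived from it).
#' @param ... Passed to [plant_syntax_pair()].
#' @return A tibble with one row per pair (`pair_id`, `kind`, `seq_a`,
#'   `seq_b`, `planted_orientation`, `planted_gap`, `magnitude`, and the
#'   model in the `model` list-column), with the scanned `gap_grid` as an
#'   attribute.
#' @export
simulate_syntax_battery <- function(n_hard = 20L, n_soft = 20L, n_null = 20L,
                                    seed = 1L, ...) {
  kinds <- rep(c("hard", "soft", "null"), times = c(n_hard, n_soft, n_null))
  args <- list(...)
  pairs <- imap(kinds, function(kind, i) {
    pair_seed <- ((as.numeric(seed) %% 100000) * 10007 + i * 7919) %% 2147483647
    p <- do.call(plant_syntax_pair,
                 c(list(kind = kind, seed = as.integer(pair_seed)), args))
    tibble(pair_id = sprintf("pair%03d", i), kind = p$kind,
           seq_a = p$seq_a, seq_b = p$seq_b,
           planted_orientation = p$orientation, planted_gap = p$gap,
           magnitude = p$magnitude, model = list(p$model))
  })
  out <- bind_rows(pairs)
  attr(out, "gap_grid") <- args$gap_grid %||% seq(0L, 200L, 10L)
  out
}

#' Run the marginalization screen over a syntax battery
#'
#' For each battery pair, draws a GC-matched background library excluding
#' both consensi, scans all orientations and the battery gap grid with
#' [marginalize_pair()], and classifies the batch with [synergy_screen()].
#' The returned calls are joined with the planted truth; `recovered` is
#' `TRUE` when the called syntax class matches the planted one (a null pair
#' counts as recovered when it is not called synergistic).
#'
#' @param battery A tibble from [simulate_syntax_battery()].
#' @param n_backgrounds Background library size per pair.
#' @param thresholds A [synergy_thresholds()] object.
#' @param seed Integer seed for the background libraries.
#' @return A tibble of class `"synergy_calls"`: one row per pair with the
#'   planted annotations and recovery flags.
#' @export
screen_syntax_battery <- function(battery, n_backgrounds = 100L,
                                  thresholds = synergy_thresholds(),
                                  seed = 1L) {
  gap_grid <- attr(battery, "gap_grid") %||% seq(0L, 200L, 10L)
  ets <- map(seq_len(nrow(battery)), function(i) {
    model <- battery$model[[i]]
    lib <- make_background_library(
      n = n_backgrounds, length = window_length(model),
      forbidden = c(battery$seq_a[i], battery$seq_b[i]),
      seed = ((as.numeric(seed) %% 100000) * 20011 + i * 104729) %% 2147483647
    )
    marginalize_pair(model, lib, battery$seq_a[i], battery$seq_b[i],
                     gaps = gap_grid)
  })
  names(ets) <- battery$pair_id
  calls <- synergy_screen(ets, thresholds)
  truth <- battery |>
    select("pair_id", "kind", "planted_orientation", "planted_gap",
           "magnitude")
  out <- left_join(calls, truth, by = c(composite = "pair_id")) |>
    mutate(
      recovered = case_when(
        .data$kind == "null" ~ !.data$synergistic,
        TRUE ~ .data$synergistic & .data$syntax == .data$kind
      ),
      optimum_matches = .data$kind == "hard" &
        .data$orientation == .data$planted_orientation &
        .data$gap == .data$planted_gap
    )
  class(out) <- c("synergy_calls", class(out))
  attr(out, "thresholds") <- thresholds
  out
}
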