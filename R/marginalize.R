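# The in silico marginalization engine. A motif's marginal effect is the
# mean change in predicted natural-log counts when its consensus is
# substituted into a library of background sequences; joint effects of motif
# pairs are scanned across all arrangements and compared against the
# log-additive expectation.

#' Marginal effect of a single motif
#'
#' Substitutes `seq` into the center of every background sequence and
#' records, per (sequence, fold), the difference in predicted natural-log
#' counts between the edited and unedited background (the marginal effect).
#'
#' @param predictor A predictor such as [planted_model()].
#' @param library Character vector of background sequences (for example from
#'   [make_background_library()]).
#' @param seq Consensus DNA string to insert.
#' @return A tibble of class `"marginal_effects"` with columns `seq_idx`,
#'   `fold`, `y0`, `yA`, `dA`. The summary mean over sequences and folds is
#'   available via [mean_effect()] or [glance()].
#' @export
marginalize_single <- function(predictor, library, seq) {
  if (length(library) == 0) .param_error("`library` must be nonempty.")
  .check_dna(seq, "seq")
  folds <- seq_len(n_folds(predictor))
  edited <- build_edited_sequence(library, seq)
  y0 <- .predict_fold_matrix(predictor, library, folds)
  ya <- .predict_fold_matrix(predictor, edited, folds)
  n <- length(library)
  out <- tibble(
    seq_idx = rep(seq_len(n), times = length(folds)),
    fold = rep(folds, each = n),
    y0 = as.vector(y0), yA = as.vector(ya),
    dA = as.vector(ya - y0)
  )
  class(out) <- c("marginal_effects", class(out))
  attr(out, "seq") <- seq
  out
}

#' Mean marginal effect
#'
#' @param x A `"marginal_effects"` table from [marginalize_single()].
#' @return The mean of `dA` over sequences and folds.
#' @export
mean_effect <- function(x) {
  stopifnot(inherits(x, "marginal_effects"))
  mean(x$dA)
}

#' Scan the joint effect of a motif pair over all arrangements
#'
#' Inserts motifs A and B jointly at every combination of orientation and
#' edge-to-edge gap, and alone, into each background sequence, predicting
#' with every model fold. For each record the joint effect `dJ = yJ - y0` is
#' compared against the log-additive independent expectation `dS = dA + dB`;
#' a significant excess of `dJ` over `dS` is the signature of synergy.
#' Single-motif effects are computed once per (sequence, fold) and shared
#' across arrangements; iteration order (sequence, fold, orientation,
#' ascending gap) is deterministic.
#'
#' @inheritParams marginalize_single
#' @param seq_a,seq_b Consensus DNA strings of the two motifs.
#' @param gaps Integer vector of edge-to-edge gaps in bp to scan
#'   (default 0 to 200).
#' @param orientations Orientation codes to scan; defaults to
#'   [enumerate_orientations()] of the pair.
#' @return A tibble of class `"effect_table"` with one row per (sequence,
#'   fold, arrangement): columns `seq_idx`, `fold`, `orientation`, `gap`,
#'   `center_distance`, `y0`, `yA`, `yB`, `yJ`, `dA`, `dB`, `dJ`, `dS`.
#' @export
marginalize_pair <- function(predictor, library, seq_a, seq_b,
                             gaps = 0:200, orientations = NULL) {
  if (length(library) == 0) .param_error("`library` must be nonempty.")
  .check_dna(seq_a, "seq_a"); .check_dna(seq_b, "seq_b")
  gaps <- sort(unique(as.integer(gaps)))
  if (any(gaps < 0)) .param_error("`gaps` must be non-negative.")
  orientations <- orientations %||% enumerate_orientations(seq_a, seq_b)
  orientations <- orientations[order(.orientation_rank(orientations))]
  folds <- seq_len(n_folds(predictor))
  n <- length(library); nf <- length(folds)
  half_len <- (nchar(seq_a) + nchar(seq_b)) / 2

  y0 <- .predict_fold_matrix(predictor, library, folds)
  ya <- .predict_fold_matrix(predictor, build_edited_sequence(library, seq_a),
                             folds)
  yb <- .predict_fold_matrix(predictor, build_edited_sequence(library, seq_b),
                             folds)

  n_arr <- length(orientations) * length(gaps)
  block <- n * nf
  yJ <- numeric(n_arr * block)
  orient_col <- character(n_arr)
  gap_col <- integer(n_arr)
  a <- 0L
  for (code in orientations) {
    for (gap in gaps) {
      edited <- build_edited_sequence(library, seq_a, seq_b,
                                      orientation = code, gap = gap)
      yj <- .predict_fold_matrix(predictor, edited, folds)
      yJ[(a * block + 1L):((a + 1L) * block)] <- as.vector(yj)
      a <- a + 1L
      orient_col[a] <- code
      gap_col[a] <- gap
    }
  }

  y0v <- rep(as.vector(y0), times = n_arr)
  yav <- rep(as.vector(ya), times = n_arr)
  ybv <- rep(as.vector(yb), times = n_arr)
  out <- tibble(
    seq_idx = rep(rep(seq_len(n), times = nf), times = n_arr),
    fold = rep(rep(folds, each = n), times = n_arr),
    orientation = rep(orient_col, each = block),
    gap = rep(gap_col, each = block),
    center_distance = rep(gap_col, each = block) + half_len,
    y0 = y0v, yA = yav, yB = ybv, yJ = yJ,
    dA = yav - y0v, dB = ybv - y0v, dJ = yJ - y0v,
    dS = (yav - y0v) + (ybv - y0v)
  )
  class(out) <- c("effect_table", class(out))
  attr(out, "seq_a") <- seq_a
  attr(out, "seq_b") <- seq_b
  out
}

#' Predicted effect of a single-nucleotide variant
#'
#' Substitutes the effect allele at the variant position and scores, per
#' model fold, (i) the sum of per-base predicted count differences in the
#' 100-bp profile window centered at the variant (truncated at profile
#' boundaries) and (ii) the log2 fold change of predicted total counts for
#' the effect versus the non-effect allele. A log2 fold change > 0 means the
#' effect allele is predicted to increase accessibility.
#'
#' @inheritParams marginalize_single
#' @param window_seq DNA sequence of the predictor window containing the
#'   variant.
#' @param variant_offset 0-based offset of the variant within `window_seq`;
#'   must fall inside the central profile window.
#' @param non_effect_base,effect_base Single bases; `window_seq` must carry
#'   `non_effect_base` at the variant offset.
#' @return A tibble of class `"variant_effect"` with one row per fold
#'   (`fold`, `delta_counts_100bp`, `log2fc_counts`); cross-fold means via
#'   [glance()].
#' @export
variant_effect <- function(predictor, window_seq, variant_offset,
                           non_effect_base, effect_base) {
  .check_dna(window_seq, "window_seq")
  stopifnot(length(window_seq) == 1L)
  w <- nchar(window_seq)
  p <- profile_length(predictor)
  c0 <- (w - p) %/% 2L
  if (variant_offset < c0 || variant_offset >= c0 + p) {
    .param_error("`variant_offset` must fall inside the central profile window.")
  }
  ref_base <- substr(window_seq, variant_offset + 1L, variant_offset + 1L)
  if (!identical(ref_base, non_effect_base)) {
    abort(sprintf(
      "Reference mismatch: window has %s at offset %d, not %s.",
      ref_base, variant_offset, non_effect_base),
      class = "motifsyntax_reference_mismatch")
  }
  alt_seq <- window_seq
  substr(alt_seq, variant_offset + 1L, variant_offset + 1L) <- effect_base
  pos <- variant_offset - c0            # 0-based in profile coordinates
  win <- max(pos - 50L, 0L):min(pos + 49L, p - 1L)
  folds <- seq_len(n_folds(predictor))
  rows <- map(folds, function(f) {
    prof_ref <- predict_profile(predictor, window_seq, f)
    prof_alt <- predict_profile(predictor, alt_seq, f)
    tibble(
      fold = f,
      delta_counts_100bp = sum(prof_alt[win + 1L] - prof_ref[win + 1L]),
      log2fc_counts = log2(sum(prof_alt) / sum(prof_ref))
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("variant_effect", class(out))
  attr(out, "variant_offset") <- variant_offset
  out
}

#' In silico ablation of motif instances
#'
#' Neutralizes motif instances by replacing every base in the instance span
#' with the base carrying the smallest absolute hypothetical contribution
#' score (the most neutral base), and records the change in predicted log
#' counts. Instances are split into quartiles of their `hit_correlation`
#' score and `per_quartile` instances are sampled from each quartile; if a
#' quartile holds fewer, all are used with a warning.
#'
#' @inheritParams marginalize_single
#' @param instances Tibble with columns `seq` (window sequence), `start`,
#'   `end` (0-based half-open span within `seq`) and `hit_correlation`.
#' @param per_quartile Number of instances sampled per quartile.
#' @param seed Seed for quartile sampling.
#' @return A tibble of class `"ablation_result"`: the sampled instances with
#'   `quartile` and `delta` (mean over folds of predicted log counts after
#'   minus before ablation).
#' @export
ablate_instances <- function(predictor, instances, per_quartile = 250L,
                             seed = 1L) {
  if (is.null(instances) || nrow(instances) == 0) {
    .param_error("`instances` must be nonempty.")
  }
  stopifnot(all(c("seq", "start", "end", "hit_correlation") %in%
                  names(instances)))
  n <- nrow(instances)
  quartile <- as.integer(ceiling(4 * rank(instances$hit_correlation,
                                          ties.method = "first") / n))
  take <- with_seed(seed, {
    unlist(lapply(1:4, function(q) {
      idx <- which(quartile == q)
      if (length(idx) == 0) return(integer())
      if (length(idx) <= per_quartile) {
        warn(sprintf(
          "Quartile %d has %d instances (< %d requested); using all.",
          q, length(idx), per_quartile))
        idx
      } else {
        sample(idx, per_quartile)
      }
    }))
  })
  folds <- seq_len(n_folds(predictor))
  deltas <- vapply(take, function(i) {
    s <- instances$seq[i]
    span <- (instances$start[i] + 1L):instances$end[i]
    hyp <- hypothetical_contributions(predictor, s, folds[1])
    if (length(folds) > 1) {
      for (f in folds[-1]) {
        hyp <- hyp + hypothetical_contributions(predictor, s, f)
      }
      hyp <- hyp / length(folds)
    }
    neutral <- .BASES[apply(abs(hyp[, span, drop = FALSE]), 2L, which.min)]
    ablated <- s
    substr(ablated, min(span), max(span)) <- paste(neutral, collapse = "")
    before <- .predict_fold_matrix(predictor, s, folds)
    after <- .predict_fold_matrix(predictor, ablated, folds)
    mean(after - before)
  }, numeric(1))
  out <- instances[take, , drop = FALSE]
  out$quartile <- quartile[take]
  out$delta <- deltas
  out <- as_tibble(out)
  class(out) <- c("ablation_result", class(out))
  out
}
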