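# Statistical synergy calling and hard/soft syntax classification on effect
# tables, plus the interpretation-consistency guard, the cross-context
# screen, and rank-based utilities.

#' Thresholds for synergy calling and syntax classification
#'
#' @param alpha_adj BH-adjusted p-value cutoff for synergy (default 0.001).
#' @param min_diff Minimum mean `dJ - dS` (natural-log counts) for synergy
#'   and for soft syntax (default 0.15).
#' @param z_hard z-score cutoff across per-arrangement mean joint effects
#'   above which an arrangement marks hard syntax (default 4).
#' @param soft_range Edge-to-edge gap range in bp within which an
#'   above-threshold arrangement marks soft syntax (default 20 to 150).
#' @return A list of class `"synergy_thresholds"`.
#' @export
synergy_thresholds <- function(alpha_adj = 0.001, min_diff = 0.15,
                               z_hard = 4, soft_range = c(20, 150)) {
  if (alpha_adj <= 0 || alpha_adj >= 1) .param_error("`alpha_adj` must be in (0,1).")
  if (min_diff <= 0) .param_error("`min_diff` must be positive.")
  if (z_hard <= 0) .param_error("`z_hard` must be positive.")
  if (length(soft_range) != 2L || soft_range[1] > soft_range[2]) {
    .param_error("`soft_range` must be an ordered pair.")
  }
  structure(list(alpha_adj = alpha_adj, min_diff = min_diff,
                 z_hard = z_hard, soft_range = soft_range),
            class = "synergy_thresholds")
}

# Per-arrangement means over sequences and folds.
.arrangement_summary <- function(effect_table) {
  effect_table |>
    group_by(.data$orientation, .data$gap) |>
    summarise(center_distance = .data$center_distance[1],
              mean_dJ = mean(.data$dJ),
              mean_diff = mean(.data$dJ - .data$dS),
              .groups = "drop")
}

#' Optimal arrangement of a motif pair
#'
#' The combination of orientation and gap with the greatest mean joint
#' effect `dJ` over sequences and folds; ties broken by smallest gap, then
#' canonical orientation order.
#'
#' @param effect_table An `"effect_table"` from [marginalize_pair()].
#' @return A one-row tibble with `orientation`, `gap`, `center_distance`,
#'   `mean_dJ`, `mean_diff`.
#' @export
optimal_arrangement <- function(effect_table) {
  if (is.null(effect_table) || nrow(effect_table) == 0) {
    .param_error("`effect_table` must be nonempty.")
  }
  s <- .arrangement_summary(effect_table)
  ord <- order(-s$mean_dJ, s$gap, .orientation_rank(s$orientation))
  s[ord[1L], ]
}

# Fast one-sided (greater) signed-rank p-value; zeros dropped. Exact
# tie-aware enumeration for n <= `exact_limit`, normal approximation with
# tie correction and continuity correction otherwise.
.wilcox_greater_p <- function(x, exact_limit = 25L) {
  x <- x[x != 0]
  n <- length(x)
  if (n == 0) return(list(p = 1, statistic = NA_real_, n = 0L,
                          method = "degenerate", degenerate = TRUE))
  r <- rank(abs(x))
  w <- sum(r[x > 0])
  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L)
    f[1L] <- 1
    for (ri in r2) {
      f[(ri + 1L):(total + 1L)] <- f[(ri + 1L):(total + 1L)] +
        f[1L:(total + 1L - ri)]
    }
    obs <- as.integer(round(2 * w))
    p <- sum(f[(obs + 1L):(total + 1L)]) / 2^n
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - 0.5) / sqrt(sigma2)
    p <- pnorm(z, lower.tail = FALSE)
    method <- "normal approximation"
  }
  list(p = p, statistic = w, n = n, method = method, degenerate = FALSE)
}

#' One-sided Wilcoxon signed-rank test
#'
#' Tests whether paired differences are significantly greater than zero.
#' Zero differences are dropped before ranking. The null distribution of the
#' signed-rank statistic is enumerated exactly (handling ties through
#' averaged ranks) for up to `exact_limit` nonzero differences; beyond that
#' a normal approximation with tie and continuity corrections is used. The
#' p-value is \eqn{P(W \ge W_{obs})} under random sign assignment.
#'
#' @param x Numeric vector of paired differences.
#' @param exact_limit Largest n for which the exact null is enumerated.
#' @return A one-row tibble: `statistic` (sum of positive ranks `W`),
#'   `p_value`, `n` (nonzero differences), `method`, `degenerate` (all
#'   differences zero, in which case `p_value` is 1).
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5))  # p = 1/32
#' @export
wilcoxon_signed_rank <- function(x, exact_limit = 25L) {
  if (!is.numeric(x) || length(x) == 0) .param_error("`x` must be numeric.")
  res <- .wilcox_greater_p(x, exact_limit)
  tibble(statistic = res$statistic, p_value = res$p, n = res$n,
         method = res$method, degenerate = res$degenerate)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, clipped to 1 and order-preserving.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    .param_error("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

# One composite's synergy call ingredients (p-adjustment happens across the
# batch in synergy_screen()).
.classify_one <- function(effect_table, thresholds, composite = NA_character_) {
  s <- .arrangement_summary(effect_table)
  opt <- optimal_arrangement(effect_table)
  diffs <- effect_table |>
    filter(.data$orientation == opt$orientation, .data$gap == opt$gap)
  wt <- .wilcox_greater_p(diffs$dJ - diffs$dS)
  sdv <- sd(s$mean_dJ)
  degenerate_z <- length(s$mean_dJ) < 2L || !is.finite(sdv) || sdv < 1e-12
  if (degenerate_z) {
    z_max <- NA_real_
    hard <- FALSE
  } else {
    z <- (s$mean_dJ - mean(s$mean_dJ)) / sdv
    z_max <- max(z)
    hard <- any(z > thresholds$z_hard)
  }
  soft <- any(s$mean_diff > thresholds$min_diff &
                s$gap >= thresholds$soft_range[1] &
                s$gap <= thresholds$soft_range[2])
  tibble(
    composite = composite,
    orientation = opt$orientation, gap = opt$gap,
    center_distance = opt$center_distance,
    mean_dJ = opt$mean_dJ, mean_diff = opt$mean_diff,
    p_raw = wt$p, p_adj = NA_real_,
    z_max = z_max, degenerate_z = degenerate_z,
    hard_arrangement = hard, soft_arrangement = soft
  )
}

.finalize_calls <- function(calls, thresholds, syntax_for_all = FALSE) {
  calls |>
    mutate(
      synergistic = .data$p_adj < thresholds$alpha_adj &
        .data$mean_diff > thresholds$min_diff,
      hard = (.data$synergistic | syntax_for_all) & .data$hard_arrangement,
      soft = (.data$synergistic | syntax_for_all) & .data$soft_arrangement,
      syntax = case_when(
        .data$status == "abstained" ~ NA_character_,
        .data$hard ~ "hard",          # hard-and-soft grouped with hard
        .data$soft ~ "soft",
        TRUE ~ "none"
      ),
      classes = pmap(list(.data$synergistic, .data$hard, .data$soft,
                          .data$status),
                     function(sy, h, so, st) {
                       if (identical(st, "abstained")) return(character())
                       c("synergistic", "hard", "soft")[c(sy, h, so)]
                     })
    )
}

#' Classify one composite motif
#'
#' Synergy is tested at the optimal arrangement with a one-sided Wilcoxon
#' signed-rank test of the paired differences `dJ - dS`; the composite is
#' synergistic if the (adjusted) p-value is below `alpha_adj` and the mean
#' difference exceeds `min_diff`. Hard syntax: any arrangement whose mean
#' joint effect lies more than `z_hard` standard deviations above the mean
#' across arrangements. Soft syntax: mean `dJ - dS` above `min_diff` at any
#' arrangement whose gap falls in `soft_range`. A composite meeting both is
#' reported as hard. When classifying a batch of composites use
#' [synergy_screen()], which applies BH correction across the batch.
#'
#' @param effect_table An `"effect_table"` from [marginalize_pair()]
#'   covering at least 2 arrangements.
#' @param thresholds A [synergy_thresholds()] object.
#' @param p_adj Adjusted p-value to use in place of the raw one (supplied by
#'   the batch screen).
#' @param syntax_for_all Report hard/soft syntax even for composites that
#'   are not synergistic.
#' @return A one-row tibble of class `"synergy_calls"`.
#' @export
classify_composite <- function(effect_table, thresholds = synergy_thresholds(),
                               p_adj = NULL, syntax_for_all = FALSE) {
  row <- .classify_one(effect_table, thresholds)
  row$p_adj <- p_adj %||% row$p_raw
  row$status <- "classified"
  out <- .finalize_calls(row, thresholds, syntax_for_all)
  class(out) <- c("synergy_calls", class(out))
  attr(out, "thresholds") <- thresholds
  out
}

#' Screen a batch of composites for synergy and syntax
#'
#' Runs [classify_composite()] for every effect table, applying
#' Benjamini-Hochberg correction across the batch (the family is the set of
#' composites screened together). Composites whose interpretation guard
#' failed are reported with status `"abstained"` and carry no classes.
#'
#' @param effect_tables Named list of `"effect_table"` objects.
#' @param thresholds A [synergy_thresholds()] object.
#' @param guards Optional named logical vector (`TRUE` = guard passed) or
#'   tibble from [interpretation_guard()] rows, aligned with
#'   `effect_tables`.
#' @param syntax_for_all Report hard/soft syntax for non-synergistic
#'   composites as well.
#' @return A tibble of class `"synergy_calls"`, one row per composite.
#' @export
synergy_screen <- function(effect_tables, thresholds = synergy_thresholds(),
                           guards = NULL, syntax_for_all = FALSE) {
  if (length(effect_tables) == 0) .param_error("No effect tables supplied.")
  ids <- names(effect_tables) %||% as.character(seq_along(effect_tables))
  calls <- bind_rows(imap(effect_tables, function(et, id) {
    .classify_one(et, thresholds, composite = id)
  }))
  calls$p_adj <- bh_adjust(calls$p_raw)
  calls$status <- "classified"
  if (!is.null(guards)) {
    pass <- if (is.data.frame(guards)) {
      setNames(guards$status == "pass", guards$composite %||% ids)
    } else {
      guards
    }
    p <- unname(pass[calls$composite])
    p[is.na(p)] <- TRUE   # composites without a guard are kept
    calls$status <- ifelse(p, "classified", "abstained")
  }
  out <- .finalize_calls(calls, thresholds, syntax_for_all)
  class(out) <- c("synergy_calls", class(out))
  attr(out, "thresholds") <- thresholds
  out
}

#' Interpretation-consistency guard
#'
#' Verifies that the sequence content driving the prediction is the content
#' that was inserted: computes the mean fraction of total absolute
#' contribution mass falling inside the inserted-position mask across
#' sequences and folds, and abstains when it falls below `min_inside_frac`.
#'
#' @param predictor A predictor exposing [contribution_scores()].
#' @param sequences Character vector of edited sequences.
#' @param mask Logical matrix (`length(sequences)` x window length) or a
#'   single logical vector recycled across sequences, `TRUE` at inserted
#'   positions.
#' @param min_inside_frac Minimum inside-mask mass fraction to pass
#'   (default 0.5; the boundary passes).
#' @return A one-row tibble: `inside_frac`, `status` (`"pass"` or
#'   `"abstain"`), `degenerate` (zero total mass).
#' @export
interpretation_guard <- function(predictor, sequences, mask,
                                 min_inside_frac = 0.5) {
  if (is.logical(mask) && is.null(dim(mask))) {
    mask <- matrix(mask, nrow = length(sequences), ncol = length(mask),
                   byrow = TRUE)
  }
  stopifnot(nrow(mask) == length(sequences))
  fracs <- c()
  for (f in seq_len(n_folds(predictor))) {
    for (i in seq_along(sequences)) {
      sc <- abs(contribution_scores(predictor, sequences[i], f))
      tot <- sum(sc)
      if (tot > 0) fracs <- c(fracs, sum(sc[mask[i, ]]) / tot)
    }
  }
  if (length(fracs) == 0) {
    return(tibble(inside_frac = NA_real_, status = "abstain",
                  degenerate = TRUE))
  }
  inside <- mean(fracs)
  tibble(inside_frac = inside,
         status = if (inside >= min_inside_frac) "pass" else "abstain",
         degenerate = FALSE)
}

#' Joint effect of one arrangement across contexts
#'
#' Repeats the joint insertion at a fixed arrangement against a list of
#' context-specific predictors (for example, models of different cell
#' types), reporting the mean and across-fold standard deviation of the
#' joint effect `dJ` in each context. A failing context is reported with
#' status `"error"`; the others continue.
#'
#' @param predictors Named list of predictors.
#' @param library Character vector of background sequences.
#' @param seq_a,seq_b Consensus DNA strings.
#' @param orientation Orientation code.
#' @param gap Edge-to-edge gap in bp.
#' @return A tibble with one row per context: `context`, `mean_dJ`, `sd_dJ`
#'   (across folds), `n_folds`, `status`.
#' @export
cross_context_screen <- function(predictors, library, seq_a, seq_b,
                                 orientation, gap) {
  if (length(predictors) == 0) .param_error("Need at least one predictor.")
  ids <- names(predictors) %||% as.character(seq_along(predictors))
  edited <- build_edited_sequence(library, seq_a, seq_b,
                                  orientation = orientation, gap = gap)
  rows <- map2(predictors, ids, function(pred, id) {
    tryCatch({
      folds <- seq_len(n_folds(pred))
      y0 <- .predict_fold_matrix(pred, library, folds)
      yj <- .predict_fold_matrix(pred, edited, folds)
      per_fold <- colMeans(yj - y0)
      tibble(context = id, mean_dJ = mean(per_fold),
             sd_dJ = sd(per_fold), n_folds = length(folds), status = "ok")
    }, error = function(e) {
      warn(sprintf("Context %s failed: %s", id, conditionMessage(e)))
      tibble(context = id, mean_dJ = NA_real_, sd_dJ = NA_real_,
             n_folds = NA_integer_, status = "error")
    })
  })
  bind_rows(rows)
}

#' Rank-sum AUROC effect size
#'
#' The Wilcoxon rank-sum W statistic divided by `n1 * n2`: the probability
#' that a random value from `x` exceeds a random value from `y`, ties
#' counted one half.
#'
#' @param x,y Numeric vectors (both nonempty).
#' @return Effect size in `[0, 1]`.
#' @export
rank_sum_auroc <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    .param_error("Both groups must be nonempty.")
  }
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  w / (n1 * n2)
}

#' Normalized prevalence or importance ranks
#'
#' Ranks motifs within each context by a statistic (instance count or summed
#' trimmed-CWM contribution), ascending so that a higher value receives a
#' higher rank, with ties averaged, and divides by the maximum rank so that
#' normalized ranks fall in `[0, 1]`. When a grouping column is supplied
#' (for example the syntax class), per-group mean normalized ranks per
#' context are attached as the `"group_means"` attribute.
#'
#' @param stats Tibble with columns `context`, `motif` and the value column.
#' @param value Column to rank by (tidy-eval; default `value`).
#' @param group Optional grouping column (tidy-eval).
#' @return `stats` with an added `norm_rank` column.
#' @export
rank_prevalence_importance <- function(stats, value = .data$value,
                                       group = NULL) {
  stopifnot(all(c("context", "motif") %in% names(stats)))
  ranked <- stats |>
    group_by(.data$context) |>
    mutate(norm_rank = {
      r <- rank({{ value }})
      r / max(r)
    }) |>
    ungroup()
  group_quo <- rlang::enquo(group)
  if (!rlang::quo_is_null(group_quo)) {
    gm <- ranked |>
      group_by(.data$context, !!group_quo) |>
      summarise(mean_norm_rank = mean(.data$norm_rank), n = n(),
                .groups = "drop")
    attr(ranked, "group_means") <- gm
  }
  ranked
}
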