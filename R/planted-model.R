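# A seeded synthetic accessibility predictor with planted motif effects and
# pairwise interactions. It satisfies the same contract as an ensemble of
# trained sequence-to-accessibility model folds -- predict(sequence, fold)
# returns natural-log total counts and a per-base profile, and per-base
# (hypothetical) contribution scores are available -- so every downstream
# procedure can be validated against known ground truth.

#' Declare a planted motif-pair interaction
#'
#' Interactions come in two flavours. A *hard* rule adds `magnitude` to the
#' predicted log counts only when the two motifs co-occur at exactly one
#' (orientation, gap) arrangement. A *soft* rule adds
#' `magnitude * exp(-gap / decay_bp)` at any orientation, a smooth distance
#' preference that decays toward independence at large separations.
#'
#' @param motif_a,motif_b Labels of motifs declared in [planted_model()].
#' @param kind `"hard"` or `"soft"`.
#' @param magnitude Interaction strength in natural-log counts.
#' @param orientation Orientation code (see [enumerate_orientations()]);
#'   required for hard rules.
#' @param gap Edge-to-edge spacing in bp; required for hard rules.
#' @param decay_bp Exponential decay length in bp for soft rules.
#' @return A one-row tibble describing the rule.
#' @export
interaction_rule <- function(motif_a, motif_b, kind = c("hard", "soft"),
                             magnitude, orientation = NULL, gap = NULL,
                             decay_bp = 40) {
  kind <- match.arg(kind)
  if (!is.finite(magnitude)) .param_error("`magnitude` must be finite.")
  if (kind == "hard") {
    if (is.null(orientation) || is.null(gap)) {
      .param_error("Hard interaction rules need `orientation` and `gap`.")
    }
    if (gap < 0 || gap > 200) {
      .param_error("Hard-rule `gap` must lie in [0, 200].")
    }
  } else {
    if (decay_bp <= 0) .param_error("`decay_bp` must be positive.")
  }
  tibble(
    motif_a = as.character(motif_a), motif_b = as.character(motif_b),
    kind = kind, magnitude = as.numeric(magnitude),
    orientation = if (is.null(orientation)) NA_character_ else orientation,
    gap = if (is.null(gap)) NA_integer_ else as.integer(gap),
    decay_bp = as.numeric(decay_bp)
  )
}

#' Build a planted accessibility predictor
#'
#' The predictor scores a sequence as `baseline` plus the signed effect of
#' every exact consensus match (both strands), plus interaction terms for
#' co-occurring motif pairs evaluated at their realized orientation and gap,
#' plus a deterministic per-(sequence, fold) Gaussian jitter that emulates
#' variability between model folds. With no motifs it is a constant
#' predictor.
#'
#' @param motifs Either a tibble with columns `label`, `consensus`, `effect`
#'   (effect in natural-log counts; negative values model repressive motifs),
#'   or a named numeric vector of effects whose names are consensus
#'   sequences.
#' @param interactions Rules built with [interaction_rule()] (rows may be
#'   combined with `dplyr::bind_rows()`).
#' @param baseline Predicted log counts of a background sequence.
#' @param fold_jitter_sd Standard deviation of the per-fold jitter, in log
#'   counts.
#' @param n_folds Number of model folds.
#' @param window_length Input sequence length in bp.
#' @param profile_length Length of the central profile window in bp.
#' @param seed Integer seed fixing the jitter and contribution noise.
#' @param cwms Optional named list of 4 x L CWM matrices (one per motif
#'   label) used to shape per-base contributions within matched spans;
#'   uniform shapes are used for motifs without a CWM.
#' @return An object of class `"planted_model"`.
#' @examples
#' mod <- planted_model(c(GATAAGAT = 0.5), fold_jitter_sd = 0, n_folds = 2,
#'                      window_length = 100, profile_length = 50)
#' @export
planted_model <- function(motifs = NULL, interactions = NULL, baseline = 2,
                          fold_jitter_sd = 0, n_folds = 5,
                          window_length = 2114, profile_length = 1000,
                          seed = 1, cwms = NULL) {
  if (is.numeric(motifs)) {
    motifs <- tibble(label = paste0("m", seq_along(motifs)),
                     consensus = names(motifs), effect = unname(motifs))
  }
  if (!is.null(motifs)) {
    stopifnot(all(c("label", "consensus", "effect") %in% names(motifs)))
    .check_dna(motifs$consensus, "consensus")
    if (!all(is.finite(motifs$effect))) .param_error("Effects must be finite.")
    if (anyDuplicated(motifs$label)) .param_error("Motif labels must be unique.")
  }
  if (!is.null(interactions) && nrow(interactions) > 0) {
    if (is.null(motifs)) .param_error("Interactions reference undeclared motifs.")
    known <- motifs$label
    if (!all(c(interactions$motif_a, interactions$motif_b) %in% known)) {
      .param_error("Interactions reference undeclared motifs.")
    }
  }
  if (profile_length > window_length) {
    .param_error("`profile_length` cannot exceed `window_length`.")
  }
  structure(
    list(motifs = motifs, interactions = interactions,
         baseline = baseline, fold_jitter_sd = fold_jitter_sd,
         n_folds = as.integer(n_folds),
         window_length = as.integer(window_length),
         profile_length = as.integer(profile_length),
         seed = as.integer(seed),
         jitter_key = ((as.numeric(seed) %% 2147483647) * 48271) %% 2147483647,
         cwms = cwms),
    class = "planted_model"
  )
}

#' @export
print.planted_model <- function(x, ...) {
  cat(sprintf(
    "<planted model> %d motifs, %d interactions, %d folds, window %d bp, jitter sd %.3g\n",
    if (is.null(x$motifs)) 0L else nrow(x$motifs),
    if (is.null(x$interactions)) 0L else nrow(x$interactions),
    x$n_folds, x$window_length, x$fold_jitter_sd))
  invisible(x)
}

#' Predictor contract accessors
#'
#' @param object A predictor implementing the accessibility-predictor
#'   contract (such as a [planted_model()]).
#' @return The number of model folds, input window length (bp) or central
#'   profile window length (bp).
#' @export
n_folds <- function(object) UseMethod("n_folds")
#' @export
n_folds.planted_model <- function(object) object$n_folds

#' @rdname n_folds
#' @export
window_length <- function(object) UseMethod("window_length")
#' @export
window_length.planted_model <- function(object) object$window_length

#' @rdname n_folds
#' @export
profile_length <- function(object) UseMethod("profile_length")
#' @export
profile_length.planted_model <- function(object) object$profile_length

# ---- deterministic per-(sequence, fold) jitter -----------------------------

.hash_env <- new.env(parent = emptyenv())

.hash_weights <- function(len) {
  w <- .hash_env$w
  if (is.null(w) || length(w) < len) {
    i <- seq_len(max(len, 4096L))
    w <- ((i * 1103515245 + 12345) %% 32768) + 1
    .hash_env$w <- w
  }
  w[seq_len(len)]
}

# Position-weighted content hash of each sequence, in [0, 2^31 - 1).
.seq_hash <- function(sequences) {
  w <- .hash_weights(max(nchar(sequences)))
  vapply(sequences, function(s) {
    x <- utf8ToInt(s)
    sum(x * w[seq_along(x)]) %% 2147483647
  }, numeric(1), USE.NAMES = FALSE)
}

# Deterministic Gaussian jitter keyed on (sequence content, fold, model seed):
# predict() stays a pure function of its arguments while distinct sequences
# receive independent noise.
.jitter_from_hash <- function(model, h, fold) {
  s <- (h + fold * 48271 + model$jitter_key) %% 2147483646 + 1
  s <- (s * 16807) %% 2147483647
  s <- (s * 48271) %% 2147483647
  u <- pmin(pmax(s / 2147483647, 1e-12), 1 - 1e-12)
  qnorm(u) * model$fold_jitter_sd
}

.planted_jitter <- function(model, sequences, fold) {
  if (model$fold_jitter_sd == 0) return(numeric(length(sequences)))
  .jitter_from_hash(model, .seq_hash(sequences), fold)
}

# Small deterministic per-base noise in [-1e-3, 1e-3], keyed on (sequence,
# fold, channel).
.planted_noise <- function(model, sequence, fold, n, channel = 1L) {
  h <- .seq_hash(sequence)
  i <- seq_len(n)
  s <- (h + fold * 48271 + channel * 7919 + i * 16807 + model$jitter_key) %%
    2147483647
  s <- (s * 48271) %% 2147483647
  (s / 2147483647 - 0.5) * 2e-3
}

# ---- consensus matching ----------------------------------------------------

# Exact matches of every declared consensus (both strands) in a set of
# sequences, as parallel plain vectors (this sits in the marginalization
# hot path). Palindromic consensi are scanned on one strand only so a single
# site is never counted twice.
.planted_matches <- function(model, sequences) {
  empty <- list(seq_idx = integer(), label = character(), start = integer(),
                end = integer(), strand = character(), effect = numeric(),
                n = 0L)
  if (is.null(model$motifs) || nrow(model$motifs) == 0) return(empty)
  dss <- Biostrings::DNAStringSet(sequences)
  seq_idx <- integer(); label <- character(); start <- integer()
  end <- integer(); strand_v <- character(); effect <- numeric()
  for (j in seq_len(nrow(model$motifs))) {
    cons <- model$motifs$consensus[j]
    w <- nchar(cons)
    rc <- .rc_string(cons)
    strands <- if (identical(rc, cons)) "+" else c("+", "-")
    for (strand in strands) {
      pat <- if (strand == "+") cons else rc
      st <- Biostrings::startIndex(Biostrings::vmatchPattern(pat, dss))
      lens <- lengths(st)
      tot <- sum(lens)
      if (tot == 0) next
      starts <- unlist(st[lens > 0], use.names = FALSE)
      seq_idx <- c(seq_idx, rep(which(lens > 0), lens[lens > 0]))
      label <- c(label, rep(model$motifs$label[j], tot))
      start <- c(start, starts - 1L)          # 0-based
      end <- c(end, starts - 1L + w)          # half-open
      strand_v <- c(strand_v, rep(strand, tot))
      effect <- c(effect, rep(model$motifs$effect[j], tot))
    }
  }
  list(seq_idx = seq_idx, label = label, start = start, end = end,
       strand = strand_v, effect = effect, n = length(seq_idx))
}

# Interaction terms for realized pairs of matched blocks. Blocks are ordered
# by position; the canonical arrangement code and edge-to-edge gap are
# compared against the declared rules. Each nonzero term is split equally
# between the two participating matches.
.interaction_terms <- function(model, m) {
  per_match <- numeric(m$n)
  rules <- model$interactions
  if (is.null(rules) || nrow(rules) == 0 || m$n == 0) {
    return(list(per_match = per_match))
  }
  for (r in seq_len(nrow(rules))) {
    la <- rules$motif_a[r]; lb <- rules$motif_b[r]
    same <- la == lb
    sel_a <- which(m$label == la)
    sel_b <- if (same) sel_a else which(m$label == lb)
    if (length(sel_a) == 0 || length(sel_b) == 0) next
    common <- intersect(unique(m$seq_idx[sel_a]), unique(m$seq_idx[sel_b]))
    kind_hard <- rules$kind[r] == "hard"
    for (sq in common) {
      ia <- sel_a[m$seq_idx[sel_a] == sq]
      ib <- sel_b[m$seq_idx[sel_b] == sq]
      pairs <- if (same) {
        if (length(ia) < 2) next
        combn(ia, 2L)
      } else {
        rbind(rep(ia, times = length(ib)), rep(ib, each = length(ia)))
      }
      for (p in seq_len(ncol(pairs))) {
        i1 <- pairs[1L, p]; i2 <- pairs[2L, p]
        if (m$start[i1] <= m$start[i2]) { left <- i1; right <- i2 }
        else { left <- i2; right <- i1 }
        gap <- m$start[right] - m$end[left]
        if (gap < 0) next  # overlapping blocks carry no planted term
        code <- .canonical_code(m$label[left] == la, m$strand[left],
                                m$strand[right], same)
        term <- if (kind_hard) {
          if (code == rules$orientation[r] && gap == rules$gap[r]) {
            rules$magnitude[r]
          } else 0
        } else {
          rules$magnitude[r] * exp(-gap / rules$decay_bp[r])
        }
        if (term != 0) {
          per_match[c(left, right)] <- per_match[c(left, right)] + term / 2
        }
      }
    }
  }
  list(per_match = per_match)
}

# Deterministic part of the predicted log counts for a set of sequences,
# together with the matches and their realized per-match effects.
.planted_base <- function(model, sequences) {
  n <- length(sequences)
  score <- rep(model$baseline, n)
  matches <- .planted_matches(model, sequences)
  inter <- .interaction_terms(model, matches)
  realized <- matches$effect + inter$per_match
  if (matches$n > 0) {
    add <- tapply(realized, matches$seq_idx, sum)
    idx <- as.integer(names(add))
    score[idx] <- score[idx] + as.numeric(add)
  }
  list(score = score, matches = matches, realized = realized)
}

.check_window <- function(model, sequences) {
  if (!all(nchar(sequences) == model$window_length)) {
    abort(sprintf("Sequences must have length %d (the predictor window).",
                  model$window_length),
          class = "motifsyntax_length_error")
  }
}

#' Predicted natural-log total counts
#'
#' @param object A predictor.
#' @param sequences Character vector of DNA sequences of the predictor's
#'   window length.
#' @param fold Fold index in `1..n_folds(object)`.
#' @return Numeric vector of predicted natural-log total counts.
#' @export
predict_log_counts <- function(object, sequences, fold = 1L) {
  UseMethod("predict_log_counts")
}

#' @export
predict_log_counts.planted_model <- function(object, sequences, fold = 1L) {
  .check_window(object, sequences)
  .planted_base(object, sequences)$score +
    .planted_jitter(object, sequences, fold)
}

# Predictions for several folds at once. The planted model's deterministic
# part (consensus matching) is shared across folds; other predictors fall
# back to one predict_log_counts() call per fold.
.predict_fold_matrix <- function(object, sequences, folds) {
  if (inherits(object, "planted_model")) {
    .check_window(object, sequences)
    base <- .planted_base(object, sequences)$score
    h <- if (object$fold_jitter_sd > 0) .seq_hash(sequences)
    m <- vapply(folds, function(f) {
      if (object$fold_jitter_sd == 0) base
      else base + .jitter_from_hash(object, h, f)
    }, numeric(length(sequences)))
  } else {
    m <- vapply(folds, function(f) predict_log_counts(object, sequences, f),
                numeric(length(sequences)))
  }
  matrix(m, nrow = length(sequences), ncol = length(folds))
}

#' Predicted per-base accessibility profile
#'
#' The profile covers the central profile window and is returned in count
#' units: near-uniform with extra mass over matched motif spans, scaled so
#' that it sums to the exponentiated predicted log counts.
#'
#' @inheritParams predict_log_counts
#' @param sequence A single DNA sequence of the predictor's window length.
#' @return Numeric vector of length `profile_length(object)`.
#' @export
predict_profile <- function(object, sequence, fold = 1L) {
  UseMethod("predict_profile")
}

#' @export
predict_profile.planted_model <- function(object, sequence, fold = 1L) {
  stopifnot(length(sequence) == 1L)
  .check_window(object, sequence)
  base <- .planted_base(object, sequence)
  y <- base$score + .planted_jitter(object, sequence, fold)
  p <- object$profile_length
  c0 <- (object$window_length - p) %/% 2L  # 0-based start of profile window
  w <- rep(1, p)
  if (base$matches$n > 0) {
    for (i in seq_len(base$matches$n)) {
      lo <- max(base$matches$start[i] - c0, 0L)
      hi <- min(base$matches$end[i] - c0, p)
      if (hi > lo) w[(lo + 1L):hi] <- w[(lo + 1L):hi] + 4
    }
  }
  w / sum(w) * exp(y)
}

#' Per-base contribution scores
#'
#' Each matched motif span receives contribution summing to its realized
#' effect (marginal effect plus half of any interaction terms it takes part
#' in), distributed proportionally to the motif's |CWM| column totals when a
#' CWM is registered with the model and uniformly otherwise. Unmatched bases
#' receive deterministic noise of magnitude at most 1e-3.
#'
#' @inheritParams predict_profile
#' @return Numeric vector of length `window_length(object)`.
#' @export
contribution_scores <- function(object, sequence, fold = 1L) {
  UseMethod("contribution_scores")
}

#' @export
contribution_scores.planted_model <- function(object, sequence, fold = 1L) {
  stopifnot(length(sequence) == 1L)
  .check_window(object, sequence)
  base <- .planted_base(object, sequence)
  scores <- .planted_noise(object, sequence, fold, object$window_length)
  if (base$matches$n > 0) {
    for (i in seq_len(base$matches$n)) {
      span <- (base$matches$start[i] + 1L):base$matches$end[i]
      cwm <- object$cwms[[base$matches$label[i]]]
      w <- if (is.null(cwm)) rep(1, length(span)) else colSums(abs(cwm))
      if (identical(base$matches$strand[i], "-")) w <- rev(w)
      if (sum(w) == 0) w <- rep(1, length(span))
      scores[span] <- base$realized[i] * w / sum(w)
    }
  }
  scores
}

#' Hypothetical per-base contribution scores
#'
#' A 4 x L matrix (rows A,C,G,T) of counterfactual contribution estimates:
#' the observed base carries the actual contribution score and the three
#' alternate bases carry near-zero noise, mirroring how attribution methods
#' report hypothetical scores for unobserved bases. Used by
#' [ablate_instances()] to pick the most neutral replacement base.
#'
#' @inheritParams predict_profile
#' @return A 4 x `window_length(object)` matrix.
#' @export
hypothetical_contributions <- function(object, sequence, fold = 1L) {
  UseMethod("hypothetical_contributions")
}

#' @export
hypothetical_contributions.planted_model <- function(object, sequence,
                                                     fold = 1L) {
  stopifnot(length(sequence) == 1L)
  .check_window(object, sequence)
  w <- object$window_length
  noise <- .planted_noise(object, sequence, fold, 4L * w, channel = 2L)
  mat <- matrix(noise, nrow = 4L, dimnames = list(.BASES, NULL))
  actual <- contribution_scores(object, sequence, fold)
  base_idx <- match(strsplit(sequence, "", fixed = TRUE)[[1]], .BASES)
  mat[cbind(base_idx, seq_len(w))] <- actual
  mat
}
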