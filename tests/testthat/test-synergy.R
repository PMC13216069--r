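# Synergy statistics against independent enumeration oracles, plus the
# classification rules, guard, cross-context screen and rank utilities.

test_that("signed-rank p equals exhaustive sign enumeration for small n, with and without ties", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p_value, 1 / 32)
  set.seed(31)
  cases <- c(
    lapply(1:6, function(i) rnorm(sample(3:10, 1))),
    lapply(1:6, function(i) round(rnorm(sample(4:10, 1)), 0)),  # ties/zeros
    list(c(1, -1), c(2, 2, -2), c(0, 0, 1, -1, 2))
  )
  for (x in cases) {
    if (all(x == 0)) next
    expect_equal(wilcoxon_signed_rank(x)$p_value, oracle_wilcoxon_greater(x),
                 info = paste(x, collapse = ","))
  }
  d <- wilcoxon_signed_rank(c(0, 0, 0))
  expect_true(d$degenerate)
  expect_equal(d$p_value, 1)
})

test_that("the large-sample approximation agrees with the exact tail", {
  set.seed(7)
  x <- rnorm(40, mean = 0.3)
  p_approx <- wilcoxon_signed_rank(x)$p_value
  p_exact <- wilcoxon_signed_rank(x, exact_limit = 64L)$p_value
  expect_equal(p_approx, p_exact, tolerance = 0.1)
  expect_equal(wilcoxon_signed_rank(x)$method, "normal approximation")
})

test_that("BH adjustment matches the hand step-up rule and is order-preserving", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(5)
  for (i in 1:5) {
    p <- runif(sample(3:20, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p))
    expect_equal(order(adj[order(p)]), seq_along(p))  # order-preserving
  }
  expect_error(bh_adjust(c(0.1, 1.2)), class = "motifsyntax_parameter_error")
})

test_that("the optimal arrangement maximizes mean dJ with deterministic tie-breaks", {
  mk_et <- function(rows) {
    out <- tibble::as_tibble(rows)
    class(out) <- c("effect_table", class(out))
    out
  }
  et <- mk_et(data.frame(
    seq_idx = 1, fold = 1,
    orientation = rep(c("A+B+", "A+B-"), each = 3),
    gap = rep(c(3, 5, 7), 2), center_distance = rep(c(8, 10, 12), 2),
    y0 = 0, yA = 1, yB = 1,
    yJ = c(2, 4, 4, 2, 2, 2)))
  et$dA <- 1; et$dB <- 1; et$dJ <- et$yJ; et$dS <- 2
  opt <- optimal_arrangement(et)
  expect_equal(opt$gap, 5)                   # tie between gaps 5 and 7
  expect_equal(opt$orientation, "A+B+")
  expect_error(optimal_arrangement(et[0, ]),
               class = "motifsyntax_parameter_error")
})

test_that("classification applies the synergy, hard and soft rules", {
  # build a synthetic effect table: 2 orientations x gaps 0..200 by 10,
  # 40 records per arrangement
  build_et <- function(diff_by_arr, noise_sd = 0.01, seed = 1) {
    set.seed(seed)
    grid <- expand.grid(gap = seq(0, 200, 10),
                        orientation = c("A+B+", "A+B-"),
                        stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      d <- diff_by_arr(grid$orientation[i], grid$gap[i])
      tibble::tibble(
        seq_idx = rep(1:20, 2), fold = rep(1:2, each = 20),
        orientation = grid$orientation[i], gap = grid$gap[i],
        center_distance = grid$gap[i] + 8,
        y0 = 0, yA = 0.5, yB = 0.5,
        yJ = 1 + d + rnorm(40, sd = noise_sd))
    })
    out <- dplyr::bind_rows(rows)
    out$dA <- 0.5; out$dB <- 0.5
    out$dJ <- out$yJ; out$dS <- 1
    class(out) <- c("effect_table", class(out))
    out
  }
  th <- synergy_thresholds()
  # spike at one arrangement: synergistic + hard (also soft: gap 50 in range)
  hard_et <- build_et(function(o, g) if (o == "A+B+" && g == 50) 0.4 else 0)
  hard_call <- classify_composite(hard_et, th)
  expect_true(hard_call$synergistic)
  expect_true(hard_call$hard)
  expect_equal(hard_call$syntax, "hard")     # hard-and-soft grouped as hard
  expect_equal(hard_call$orientation, "A+B+")
  expect_equal(hard_call$gap, 50)
  # plateau inside the soft range, z small: soft only
  soft_et <- build_et(function(o, g) 0.3 * exp(-g / 40))
  soft_call <- classify_composite(soft_et, th)
  expect_true(soft_call$synergistic)
  expect_false(soft_call$hard)
  expect_equal(soft_call$syntax, "soft")
  # strong effect but non-significant threshold combination:
  # mean_diff below min_diff
  null_et <- build_et(function(o, g) 0.05)
  null_call <- classify_composite(null_et, th)
  expect_false(null_call$synergistic)
  expect_equal(null_call$syntax, "none")
})

test_that("screening applies BH across the batch and guards force abstention", {
  build_simple <- function(d, seed) {
    set.seed(seed)
    out <- tibble::tibble(
      seq_idx = rep(1:10, 6), fold = 1,
      orientation = rep(c("A+B+", "A+B-"), each = 10 * 3),
      gap = rep(rep(c(0, 30, 60), each = 10), 2),
      center_distance = 0, y0 = 0, yA = 0.5, yB = 0.5,
      yJ = 1 + rep(rep(c(d, 0, 0), each = 10), 2) + rnorm(60, sd = 0.01))
    out$dA <- 0.5; out$dB <- 0.5; out$dJ <- out$yJ; out$dS <- 1
    class(out) <- c("effect_table", class(out))
    out
  }
  ets <- list(one = build_simple(0.4, 1), two = build_simple(0, 2))
  calls <- synergy_screen(ets)
  expect_equal(calls$p_adj, bh_adjust(calls$p_raw))
  calls_g <- synergy_screen(ets, guards = c(one = FALSE, two = TRUE))
  expect_equal(calls_g$status, c("abstained", "classified"))
  expect_true(is.na(calls_g$syntax[1]))
  expect_length(calls_g$classes[[1]], 0)
})

test_that("the interpretation guard passes planted insertions and abstains on off-mask mass", {
  W <- 300L
  m <- planted_model(c(GATAAGAT = 0.5), fold_jitter_sd = 0, n_folds = 2,
                     window_length = W, profile_length = 100L)
  lib <- make_background_library(n = 3, length = W,
                                 forbidden = "GATAAGAT", seed = 13)
  ed <- build_edited_sequence(lib, "GATAAGAT")
  s0 <- (W - 8L) %/% 2L
  mask <- rep(FALSE, W); mask[(s0 + 1):(s0 + 8)] <- TRUE
  expect_equal(interpretation_guard(m, ed, mask)$status, "pass")
  # rigged: mask placed away from the inserted motif
  off_mask <- rep(FALSE, W); off_mask[1:8] <- TRUE
  expect_equal(interpretation_guard(m, ed, off_mask)$status, "abstain")
  # boundary: exactly the threshold passes
  half <- interpretation_guard(m, ed, mask, min_inside_frac = 1)
  expect_true(half$inside_frac < 1)   # background noise carries some mass
  expect_equal(interpretation_guard(m, ed, mask,
                                    min_inside_frac = half$inside_frac)$status,
               "pass")
})

test_that("the cross-context screen reports one row per context with planted effects visible", {
  W <- 300L
  lib <- rep(strrep("A", W), 5)
  mk <- function(rule) {
    planted_model(c(GATAAGAT = 0.5, TTGACCAA = 0.7), interactions = rule,
                  fold_jitter_sd = 0, n_folds = 2, window_length = W,
                  profile_length = 100L)
  }
  preds <- list(
    none = planted_model(NULL, fold_jitter_sd = 0, n_folds = 2,
                         window_length = W, profile_length = 100L),
    additive = mk(NULL),
    synergy = mk(interaction_rule("m1", "m2", "hard", magnitude = 0.4,
                                  orientation = "A+B+", gap = 10L)))
  res <- cross_context_screen(preds, lib, "GATAAGAT", "TTGACCAA",
                              orientation = "A+B+", gap = 10L)
  expect_equal(nrow(res), 3L)
  expect_equal(res$mean_dJ[res$context == "none"], 0)
  expect_equal(res$mean_dJ[res$context == "additive"], 1.2)
  expect_equal(res$mean_dJ[res$context == "synergy"], 1.6)
})

test_that("rank-sum AUROC equals brute-force pair counting", {
  expect_equal(rank_sum_auroc(c(5, 6, 7), c(1, 2)), 1)
  expect_equal(rank_sum_auroc(c(1, 3), 2), 0.5)
  expect_equal(rank_sum_auroc(1, 1), 0.5)
  set.seed(17)
  for (i in 1:10) {
    x <- sample(1:8, sample(2:40, 1), replace = TRUE)
    y <- sample(1:8, sample(2:40, 1), replace = TRUE)
    expect_equal(rank_sum_auroc(x, y), oracle_auroc(x, y))
  }
  expect_error(rank_sum_auroc(numeric(), 1),
               class = "motifsyntax_parameter_error")
})

test_that("normalized ranks fall in [0,1] with higher counts ranked higher", {
  stats <- tibble::tibble(
    context = rep(c("c1", "c2"), c(3, 1)),
    motif = c("a", "b", "c", "a"),
    value = c(10, 20, 30, 5),
    group = c("hard", "soft", "none", "hard"))
  ranked <- rank_prevalence_importance(stats, value, group = group)
  expect_equal(ranked$norm_rank[ranked$context == "c1"], c(1, 2, 3) / 3)
  expect_equal(ranked$norm_rank[ranked$context == "c2"], 1)
  gm <- attr(ranked, "group_means")
  expect_equal(nrow(gm), 4L)
  set.seed(2)
  r2 <- rank_prevalence_importance(
    tibble::tibble(context = "c", motif = letters[1:10], value = rnorm(10)))
  expect_true(all(r2$norm_rank > 0 & r2$norm_rank <= 1))
})
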