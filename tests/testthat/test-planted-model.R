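# The planted predictor must satisfy the predictor contract exactly:
# deterministic given (sequence, fold, seed), additive planted effects, and
# contribution mass concentrated on matched spans.

W <- 300L  # small window keeps these tests fast

new_model <- function(...) {
  planted_model(..., window_length = W, profile_length = 100L)
}

bg <- function(n = 5, seed = 3, forbidden = c("GATAAGAT", "TTGACCAA")) {
  make_background_library(n = n, length = W, forbidden = forbidden,
                          seed = seed)
}

test_that("planted log counts follow the closed form of the planted model", {
  m <- new_model(c(GATAAGAT = 0.5, TTGACCAA = 0.7),
                 interactions = interaction_rule(
                   "m1", "m2", "hard", magnitude = 0.4,
                   orientation = "A+B+", gap = 5L),
                 baseline = 2, fold_jitter_sd = 0, n_folds = 2)
  lib <- bg()
  # background: baseline exactly (no motif terms)
  expect_equal(predict_log_counts(m, lib, 1), rep(2, 5))
  # one match: baseline + effect
  ed <- build_edited_sequence(lib, "GATAAGAT")
  expect_equal(predict_log_counts(m, ed, 1), rep(2.5, 5))
  # pair at the hard arrangement: baseline + 0.5 + 0.7 + 0.4
  edj <- build_edited_sequence(lib, "GATAAGAT", "TTGACCAA",
                               orientation = "A+B+", gap = 5L)
  expect_equal(predict_log_counts(m, edj, 1), rep(3.6, 5))
  # same pair elsewhere: no interaction term
  ed2 <- build_edited_sequence(lib, "GATAAGAT", "TTGACCAA",
                               orientation = "A+B+", gap = 10L)
  expect_equal(predict_log_counts(m, ed2, 1), rep(3.2, 5))
  expect_error(predict_log_counts(m, "ACGT", 1),
               class = "motifsyntax_length_error")
})

test_that("predictions are deterministic given (sequence, fold, seed) and vary across folds", {
  m <- new_model(c(GATAAGAT = 0.5), fold_jitter_sd = 0.1, n_folds = 3)
  lib <- bg()
  y1 <- predict_log_counts(m, lib, 1)
  expect_identical(y1, predict_log_counts(m, lib, 1))
  expect_false(any(y1 == predict_log_counts(m, lib, 2)))
  m2 <- new_model(c(GATAAGAT = 0.5), fold_jitter_sd = 0.1, n_folds = 3,
                  seed = 99)
  expect_false(any(y1 == predict_log_counts(m2, lib, 1)))
})

test_that("contribution mass lands on matched spans and sums to realized effects", {
  m <- new_model(c(GATAAGAT = 0.5, TTGACCAA = -0.3), fold_jitter_sd = 0)
  lib <- bg(n = 2)
  # no matches: all |scores| <= 1e-3
  sc0 <- contribution_scores(m, lib[1], 1)
  expect_true(all(abs(sc0) <= 1e-3))
  # single positive match sums to +0.5; negative match to -0.3
  ed <- build_edited_sequence(lib, "GATAAGAT", "TTGACCAA",
                              orientation = "A+B+", gap = 20L)
  sc <- contribution_scores(m, ed[1], 1)
  s1 <- regexpr("GATAAGAT", ed[1], fixed = TRUE)[1]
  s2 <- regexpr("TTGACCAA", ed[1], fixed = TRUE)[1]
  expect_equal(sum(sc[s1:(s1 + 7)]), 0.5, tolerance = 1e-6)
  expect_equal(sum(sc[s2:(s2 + 7)]), -0.3, tolerance = 1e-6)
})

test_that("the profile is nonnegative, covers the central window, and sums to exp(log counts)", {
  m <- new_model(c(GATAAGAT = 0.5), fold_jitter_sd = 0)
  lib <- bg(n = 1)
  ed <- build_edited_sequence(lib, "GATAAGAT")
  prof <- predict_profile(m, ed, 1)
  expect_length(prof, 100L)
  expect_true(all(prof >= 0))
  expect_equal(sum(prof), exp(2.5), tolerance = 1e-9)
})

test_that("hypothetical contributions carry the actual score on the observed base", {
  m <- new_model(c(GATAAGAT = 0.5), fold_jitter_sd = 0)
  lib <- bg(n = 1)
  ed <- build_edited_sequence(lib, "GATAAGAT")
  hyp <- hypothetical_contributions(m, ed, 1)
  act <- contribution_scores(m, ed, 1)
  base_idx <- match(strsplit(ed, "")[[1]], c("A", "C", "G", "T"))
  expect_equal(hyp[cbind(base_idx, seq_len(W))], act)
  # alternates stay near zero inside the matched span
  s1 <- regexpr("GATAAGAT", ed, fixed = TRUE)[1]
  for (j in s1:(s1 + 7)) {
    alt <- setdiff(1:4, base_idx[j])
    expect_true(all(abs(hyp[alt, j]) <= 1e-3))
  }
})

test_that("background libraries honour size, GC, exclusion and determinism", {
  lib <- make_background_library(n = 20, length = 500, gc_target = 0.5,
                                 tolerance = 0.02,
                                 forbidden = c("GATAAGAT", "TTGACCAA"),
                                 seed = 5)
  expect_length(lib, 20L)
  expect_true(all(nchar(lib) == 500L))
  gc <- vapply(strsplit(lib, ""), function(ch) mean(ch %in% c("G", "C")),
               numeric(1))
  expect_true(all(abs(gc - 0.5) <= 0.02))
  for (pat in c("GATAAGAT", "TTGACCAA")) {
    expect_false(any(grepl(pat, lib, fixed = TRUE)))
    expect_false(any(grepl(reverse_complement(pat), lib, fixed = TRUE)))
  }
  expect_identical(as.character(lib), as.character(
    make_background_library(n = 20, length = 500, gc_target = 0.5,
                            tolerance = 0.02,
                            forbidden = c("GATAAGAT", "TTGACCAA"), seed = 5)))
  # unsatisfiable constraint errors out naming it
  expect_error(
    make_background_library(n = 1, length = 100, gc_target = 0.5,
                            tolerance = 1e-6, seed = 1, max_tries = 5),
    class = "motifsyntax_constraint_error")
})

test_that("fragment simulation applies the 9-bp duplication convention", {
  fr <- simulate_fragments(tibble::tibble(chrom = "chr1",
                                          center = c(100, 300)))
  expect_equal(nrow(fr$fragments), 1L)
  expect_equal(fr$fragments$start, 96L)     # 100 - 4
  expect_equal(fr$fragments$end, 305L)      # 300 + 4, end-exclusive
  # empty events give empty outputs
  empty <- simulate_fragments(tibble::tibble(chrom = character(),
                                             center = integer()))
  expect_equal(nrow(empty$fragments), 0L)
  expect_equal(nrow(empty$insertions), 0L)
  # duplicate centers are skipped with a warning
  expect_warning(
    simulate_fragments(tibble::tibble(chrom = "chr1",
                                      center = c(100, 100, 300))),
    "colliding")
})

test_that("simulated eQTL tables respect fidelity, size and determinism", {
  inst <- tibble::tibble(chrom = "chr1",
                         start = c(1000L, 4000L), end = c(1010L, 4012L),
                         label = c("mA", "mB"),
                         polarity = c("positive", "positive"))
  tab <- simulate_eqtl_table(inst, n_variants = 50, frac_in_instances = 1,
                             direction_fidelity = 1, seed = 2)
  expect_equal(nrow(tab), 50L)
  expect_true(all(tab$pip >= 0 & tab$pip <= 1))
  # fidelity 1 in positive motifs: every in-instance variant downregulates
  expect_true(all(tab$afc < 0))
  expect_identical(tab, simulate_eqtl_table(inst, n_variants = 50,
                                            frac_in_instances = 1,
                                            direction_fidelity = 1, seed = 2))
  expect_error(simulate_eqtl_table(inst[0, ], 10, frac_in_instances = 0.5),
               class = "motifsyntax_parameter_error")
})
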