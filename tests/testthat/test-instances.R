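# Hit calling, quality filtering and deduplication against brute-force
# oracles on constructed contribution tracks.

# A track with CWM-shaped bumps planted at known offsets.
plant_track <- function(n, placements) {
  tr <- matrix(0, 4, n)
  for (p in placements) {
    cwm <- if (identical(p$strand, "-")) {
      motifsyntax:::.rc_matrix(p$cwm)
    } else p$cwm
    span <- (p$offset + 1):(p$offset + ncol(cwm))
    tr[, span] <- tr[, span] + p$scale * cwm
  }
  tr
}

test_that("the greedy caller recovers planted bumps exactly (checked against a full scan)", {
  m1 <- trim_cwm(make_test_motif("m1", "GATAAG"))
  tr <- plant_track(200, list(list(cwm = m1$cwm, offset = 37, scale = 0.8)))
  hits <- greedy_hit_caller(tr, list(m1 = m1), min_similarity = 0.8)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 37L)
  expect_equal(hits$label, "m1")
  expect_equal(hits$hit_correlation, 1, tolerance = 1e-9)
  # brute-force confirmation that 37 is the global correlation optimum
  L <- ncol(m1$cwm)
  rs <- vapply(0:(200 - L), function(off) {
    suppressWarnings(cor(as.vector(tr[, (off + 1):(off + L)]),
                         as.vector(m1$cwm)))
  }, numeric(1))
  expect_equal(which.max(rs) - 1L, 37L)

  # all-zero track yields no instances
  expect_equal(nrow(greedy_hit_caller(matrix(0, 4, 100), list(m1 = m1))), 0L)
})

test_that("two disjoint bumps of different motifs are both recovered with correct labels and strands", {
  m1 <- trim_cwm(make_test_motif("m1", "GATAAG"))
  m2 <- trim_cwm(make_test_motif("m2", "CCAATT"))
  tr <- plant_track(300, list(
    list(cwm = m1$cwm, offset = 40, scale = 1),
    list(cwm = m2$cwm, offset = 150, scale = 0.6, strand = "-")))
  hits <- greedy_hit_caller(tr, list(m1 = m1, m2 = m2), min_similarity = 0.8)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$label[order(hits$start)], c("m1", "m2"))
  expect_equal(hits$start[order(hits$start)], c(40L, 150L))
  expect_equal(hits$strand[order(hits$start)], c("+", "-"))
})

test_that("quality_filter retains motifs whose instances reproduce their CWM and drops permuted ones", {
  set.seed(23)
  good <- trim_cwm(make_test_motif("good", "GATAAG"))
  bad <- trim_cwm(make_test_motif("bad", "CCAATT"))
  L <- ncol(good$cwm)
  n_inst <- 6L
  tr <- matrix(rnorm(4 * 600, sd = 1e-4), 4, 600)
  starts_good <- seq(10, 110, 20)
  starts_bad <- seq(300, 400, 20)
  for (s in starts_good) tr[, (s + 1):(s + L)] <- good$cwm
  for (s in starts_bad) {
    perm <- bad$cwm[sample(4), sample(ncol(bad$cwm))]
    tr[, (s + 1):(s + L)] <- perm
  }
  inst <- tibble::tibble(
    chrom = "chr1",
    start = c(starts_good, starts_bad),
    end = c(starts_good, starts_bad) + L,
    strand = "+",
    label = rep(c("good", "bad"), each = n_inst),
    hit_correlation = 0.95, contribution = 1)
  out <- quality_filter(inst, list(good = good, bad = bad), tr, min_r = 0.9)
  expect_setequal(unique(out$label), "good")
  qc <- motif_qc(out)
  expect_false(qc$dropped[qc$label == "good"])
  expect_true(qc$dropped[qc$label == "bad"])
  expect_gt(qc$instance_r[qc$label == "good"], 0.99)
  expect_lt(qc$instance_r[qc$label == "bad"], 0.9)
  # zero-instance motifs are dropped with their own flag
  extra <- trim_cwm(make_test_motif("ghost", "TTGGCC"))
  out2 <- quality_filter(inst, list(good = good, ghost = extra), tr)
  expect_equal(motif_qc(out2)$reason[motif_qc(out2)$label == "ghost"],
               "no_instances")
})

test_that("overlap dedup keeps the best instance, tolerates 3-bp overlaps, and matches the exhaustive oracle", {
  two <- tibble::tibble(chrom = "chr1", start = c(10L, 16L), end = c(20L, 26L),
                        strand = "+", label = "m",
                        hit_correlation = c(0.9, 0.8), contribution = 1)
  kept <- dedup_overlaps(two)              # 4-bp overlap: conflict
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$hit_correlation, 0.9)

  exact3 <- tibble::tibble(chrom = "chr1", start = c(10L, 17L),
                           end = c(20L, 27L), strand = "+", label = "m",
                           hit_correlation = c(0.9, 0.8), contribution = 1)
  expect_equal(nrow(dedup_overlaps(exact3)), 2L)  # overlap exactly 3 allowed

  # random chains of <= 5 instances equal the remove-best-then-recurse oracle
  set.seed(41)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    starts <- cumsum(c(10, sample(1:8, k - 1, TRUE)))
    inst <- tibble::tibble(
      chrom = "chr1", start = as.integer(starts),
      end = as.integer(starts + 8L), strand = "+",
      label = sample(c("m", "n"), k, TRUE),
      hit_correlation = round(runif(k), 2), contribution = 1)
    got <- dedup_overlaps(inst)
    want <- oracle_dedup(inst)
    expect_equal(dplyr::arrange(got, start, label),
                 dplyr::arrange(tibble::as_tibble(want), start, label),
                 info = paste("case", i))
  }
})

test_that("dedup output is invariant to input row order", {
  set.seed(12)
  starts <- c(10L, 14L, 18L, 40L)
  inst <- tibble::tibble(
    chrom = "chr1", start = starts, end = starts + 8L, strand = "+",
    label = "m", hit_correlation = c(0.7, 0.95, 0.8, 0.5), contribution = 1)
  base <- dedup_overlaps(inst)
  for (i in 1:5) {
    perm <- inst[sample(nrow(inst)), ]
    expect_equal(dedup_overlaps(perm), base)
  }
})
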