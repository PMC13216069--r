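# Independent brute-force / enumeration oracles used to validate the
# package's statistics. These deliberately re-derive each quantity from
# first principles and stay independent of the implementation under test.

# One-sided signed-rank p by exhaustive enumeration of all 2^n sign
# assignments: P(W >= W_obs) with averaged ranks for tied magnitudes.
oracle_wilcoxon_greater <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  if (n == 0) return(1)
  r <- rank(abs(x))
  obs <- sum(r[x > 0])
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  ws <- apply(grid, 1L, function(s) sum(r[unlist(s)]))
  mean(ws >= obs - 1e-9)
}

# Hand application of the BH step-up rule with cumulative minimum.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# One-sided (enrichment) Fisher p from the hypergeometric upper tail.
oracle_fisher_greater <- function(both, a_only, b_only, neither) {
  N <- both + a_only + b_only + neither
  K <- both + a_only
  m <- both + b_only
  xs <- both:min(K, m)
  sum(stats::dhyper(xs, K, N - K, m))
}

# Two-sided Fisher p: sum of table probabilities not exceeding the observed
# one (with the same relative slack R uses).
oracle_fisher_two_sided <- function(tbl) {
  both <- tbl[1, 1]; a_only <- tbl[1, 2]; b_only <- tbl[2, 1]
  neither <- tbl[2, 2]
  N <- sum(tbl); K <- both + a_only; m <- both + b_only
  xs <- max(0, K + m - N):min(K, m)
  probs <- stats::dhyper(xs, K, N - K, m)
  p_obs <- stats::dhyper(both, K, N - K, m)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUROC by brute-force pair counting with half-weight ties.
oracle_auroc <- function(x, y) {
  mean(outer(x, y, ">") + 0.5 * outer(x, y, "=="))
}

# Overlap deduplication by repeatedly retaining the highest-priority
# instance and discarding its same-label conflicts (priority: higher
# hit_correlation, then leftmost start, then end, then input order).
oracle_dedup <- function(instances, max_overlap = 3L) {
  idx <- seq_len(nrow(instances))
  kept <- integer()
  remaining <- idx
  while (length(remaining) > 0) {
    sub <- instances[remaining, ]
    best <- remaining[order(-sub$hit_correlation, sub$start, sub$end,
                            remaining)][1]
    kept <- c(kept, best)
    conflict <- vapply(remaining, function(j) {
      if (j == best) return(TRUE)
      if (instances$label[j] != instances$label[best] ||
          instances$chrom[j] != instances$chrom[best]) return(FALSE)
      ov <- min(instances$end[j], instances$end[best]) -
        max(instances$start[j], instances$start[best])
      ov > max_overlap
    }, logical(1))
    remaining <- remaining[!conflict]
  }
  instances[sort(kept), ]
}

# Exhaustive direction-assignment oracle for the permutation enrichment p:
# every distinct assignment of the observed up/down labels to variant
# positions, p = #{assignments with count >= observed} / N.
oracle_perm_p <- function(pairs, instances, label, direction) {
  n <- nrow(pairs)
  n_up <- sum(pairs$afc > 0)
  inst <- instances[instances$label == label, ]
  overlaps <- vapply(seq_len(n), function(i) {
    any(inst$chrom == pairs$chrom[i] & inst$start <= pairs$pos[i] &
          pairs$pos[i] < inst$end)
  }, logical(1))
  count_for <- function(up_set) {
    if (direction == "up") sum(overlaps & up_set) else sum(overlaps & !up_set)
  }
  obs <- count_for(pairs$afc > 0)
  sets <- utils::combn(n, n_up)
  counts <- apply(sets, 2L, function(s) {
    up <- rep(FALSE, n); up[s] <- TRUE
    count_for(up)
  })
  sum(counts >= obs) / length(counts)
}

# Small random motif whose CWM is concentrated on a consensus.
make_test_motif <- function(label = "m1", consensus = "GATAAG",
                            polarity = "positive", n_seqlets = 10L,
                            strength = 1) {
  L <- nchar(consensus)
  cwm <- matrix(0.01, 4L, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  cwm[cbind(idx, seq_len(L))] <- strength
  if (polarity == "negative") cwm <- -cwm
  ppm <- matrix(0.05, 4L, L)
  ppm[cbind(idx, seq_len(L))] <- 0.85
  motif(label, cwm, ppm, polarity = polarity, n_seqlets = n_seqlets)
}
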