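# Genomic annotation of motif instances: promoter/exonic/intronic/distal
# context, distances to anchors, distance binning, motif co-occurrence
# testing, and Tn5 footprint metaplots.

#' Assemble a genome annotation
#'
#' @param tss Tibble of transcription start sites: `chrom`, `pos` (0-based).
#' @param exons,gene_bodies Tibbles of intervals: `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param dyads,summits Optional anchor tibbles: `chrom`, `pos`.
#' @return A list of class `"genome_annotation"`.
#' @export
genome_annotation <- function(tss, exons, gene_bodies, dyads = NULL,
                              summits = NULL) {
  check_pos <- function(x, nm) {
    if (!is.null(x) && !all(c("chrom", "pos") %in% names(x))) {
      .param_error(paste0("`", nm, "` needs columns chrom, pos."))
    }
  }
  check_iv <- function(x, nm) {
    if (!all(c("chrom", "start", "end") %in% names(x))) {
      .param_error(paste0("`", nm, "` needs columns chrom, start, end."))
    }
    if (any(x$start >= x$end) || any(x$start < 0)) {
      .param_error(paste0("`", nm, "` has invalid intervals."))
    }
  }
  check_pos(tss, "tss"); check_pos(dyads, "dyads"); check_pos(summits, "summits")
  check_iv(exons, "exons"); check_iv(gene_bodies, "gene_bodies")
  structure(list(tss = tss, exons = exons, gene_bodies = gene_bodies,
                 dyads = dyads, summits = summits),
            class = "genome_annotation")
}

.nearest_dist <- function(chrom, center, anchors) {
  if (is.null(anchors)) return(NA_real_)
  pos <- anchors$pos[anchors$chrom == chrom]
  if (length(pos) == 0) return(NA_real_)
  min(abs(center - pos))
}

.in_interval <- function(chrom, center, iv) {
  any(iv$chrom == chrom & iv$start <= center & center < iv$end)
}

#' Annotate motif instances with genomic context
#'
#' Each instance, evaluated at its center, is labelled `promoter` if within
#' 2 kb (upstream or downstream) of a TSS, `exonic` if it overlaps an exon,
#' `intronic` if it overlaps a gene body but not an exon, and `distal`
#' otherwise -- with that precedence. Distances from the instance center to
#' the nearest TSS, nucleosome dyad and peak summit are attached where
#' anchors are available. Instances on chromosomes absent from the
#' annotation are labelled distal with a warning.
#'
#' @param instances Instance tibble with `chrom`, `start`, `end`.
#' @param annotation A [genome_annotation()].
#' @param promoter_dist Promoter distance cutoff in bp (default 2000).
#' @return `instances` with added columns `context`, `dist_tss`,
#'   `dist_dyad`, `dist_summit`.
#' @export
annotate_context <- function(instances, annotation, promoter_dist = 2000) {
  stopifnot(inherits(annotation, "genome_annotation"))
  known <- unique(c(annotation$tss$chrom, annotation$exons$chrom,
                    annotation$gene_bodies$chrom))
  missing_chroms <- setdiff(unique(instances$chrom), known)
  if (length(missing_chroms) > 0) {
    warn(paste0("Chromosomes absent from annotation (labelled distal): ",
                paste(missing_chroms, collapse = ", ")))
  }
  n <- nrow(instances)
  context <- character(n)
  d_tss <- d_dyad <- d_summit <- numeric(n)
  for (i in seq_len(n)) {
    ch <- instances$chrom[i]
    center <- (instances$start[i] + instances$end[i]) %/% 2
    d_tss[i] <- .nearest_dist(ch, center, annotation$tss)
    d_dyad[i] <- .nearest_dist(ch, center, annotation$dyads)
    d_summit[i] <- .nearest_dist(ch, center, annotation$summits)
    context[i] <- if (!ch %in% known) {
      "distal"
    } else if (!is.na(d_tss[i]) && d_tss[i] <= promoter_dist) {
      "promoter"
    } else if (.in_interval(ch, center, annotation$exons)) {
      "exonic"
    } else if (.in_interval(ch, center, annotation$gene_bodies)) {
      "intronic"
    } else {
      "distal"
    }
  }
  instances |>
    mutate(context = context, dist_tss = d_tss, dist_dyad = d_dyad,
           dist_summit = d_summit)
}

#' Bin instance-to-anchor distances
#'
#' Counts motif instances in `bin_width`-bp half-open bins of distance from
#' the nearest anchor (nucleosome dyad or peak summit), from 0 to
#' `max_dist`; distances at or beyond `max_dist` are excluded. Counts are
#' z-scored across bins within each motif; a motif whose counts are
#' constant and positive has z = 0 everywhere, and a motif with no in-range
#' instances has undefined (NA) z.
#'
#' @param instances Instance tibble with `chrom`, `start`, `end`, `label`.
#' @param anchors Tibble of anchors: `chrom`, `pos`.
#' @param bin_width Bin width in bp (default 10).
#' @param max_dist Exclusive upper distance bound in bp (default 250).
#' @return A tibble with one row per (label, bin): `label`, `bin_start`,
#'   `bin_end`, `count`, `z`.
#' @export
bin_distances <- function(instances, anchors, bin_width = 10L,
                          max_dist = 250L) {
  if (is.null(anchors) || nrow(anchors) == 0) {
    .param_error("`anchors` must be nonempty.")
  }
  starts <- seq(0L, max_dist - bin_width, by = bin_width)
  labels <- unique(instances$label)
  dist <- vapply(seq_len(nrow(instances)), function(i) {
    .nearest_dist(instances$chrom[i],
                  (instances$start[i] + instances$end[i]) %/% 2, anchors)
  }, numeric(1))
  grid <- tidyr::expand_grid(label = labels, bin_start = starts)
  counts <- tibble(label = instances$label, dist = dist) |>
    filter(!is.na(.data$dist), .data$dist < max_dist) |>
    mutate(bin_start = (.data$dist %/% bin_width) * bin_width) |>
    group_by(.data$label, .data$bin_start) |>
    summarise(count = n(), .groups = "drop")
  grid |>
    left_join(counts, by = c("label", "bin_start")) |>
    mutate(count = ifelse(is.na(.data$count), 0L, .data$count),
           bin_end = .data$bin_start + bin_width) |>
    group_by(.data$label) |>
    mutate(z = {
      s <- sd(.data$count)
      if (is.na(s) || s == 0) {
        if (mean(.data$count) > 0) rep(0, n()) else rep(NA_real_, n())
      } else {
        (.data$count - mean(.data$count)) / s
      }
    }) |>
    ungroup() |>
    select("label", "bin_start", "bin_end", "count", "z")
}

#' Pairwise motif co-occurrence across peaks
#'
#' For every unordered motif pair, populates a 2 x 2 contingency table with
#' the number of peaks containing both, one, or neither motif and performs
#' a one-sided (enrichment) Fisher's exact test; p-values are BH-adjusted
#' across all pairs and significance called at adjusted p < 0.05.
#'
#' @param incidence Logical (or 0/1) peak-by-motif matrix or data frame;
#'   columns are motifs.
#' @return A tibble with one row per pair: counts, `odds_ratio`, `p_value`,
#'   `p_adj`, `significant`.
#' @export
cooccurrence_fisher <- function(incidence) {
  m <- as.matrix(incidence)
  if (nrow(m) < 1L) .param_error("`incidence` must contain at least one peak.")
  if (ncol(m) < 2L) .param_error("`incidence` must contain at least two motifs.")
  m <- m > 0
  labs <- colnames(m) %||% paste0("motif", seq_len(ncol(m)))
  pairs <- combn(seq_len(ncol(m)), 2L)
  rows <- map(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    both <- sum(m[, i] & m[, j])
    a_only <- sum(m[, i] & !m[, j])
    b_only <- sum(!m[, i] & m[, j])
    neither <- sum(!m[, i] & !m[, j])
    ft <- fisher.test(matrix(c(both, a_only, b_only, neither), nrow = 2L),
                      alternative = "greater")
    tibble(motif_a = labs[i], motif_b = labs[j],
           n_both = both, n_a_only = a_only, n_b_only = b_only,
           n_neither = neither,
           odds_ratio = unname(ft$estimate), p_value = ft$p.value)
  })
  out <- bind_rows(rows)
  out$p_adj <- bh_adjust(out$p_value)
  out$significant <- out$p_adj < 0.05
  out
}

#' Footprint metaplot around motif instances
#'
#' Sums Tn5 insertion counts at each position of `window`-bp windows
#' centered at motif instances, and normalizes by the mean insertion count
#' over the outer `flank_frac` of positions on each side of the window --
#' the local background accessibility. Windows truncated by track ends are
#' skipped with a warning.
#'
#' @param insertions Either a tibble with `chrom`, `pos`, `count` or a named
#'   list of per-base count vectors (element `i` = count at 0-based
#'   position `i - 1`).
#' @param instances Instance tibble with `chrom`, `start`, `end`.
#' @param window Window width in bp (default 500).
#' @param flank_frac Fraction of positions on each side used for
#'   normalization (default 0.1).
#' @return A tibble of class `"footprint"`: `position` (bp relative to the
#'   instance center), `insertions`, `normalized`.
#' @export
footprint_metaplot <- function(insertions, instances, window = 500L,
                               flank_frac = 0.1) {
  if (is.data.frame(insertions)) {
    tracks <- list()
    for (ch in unique(insertions$chrom)) {
      sub <- insertions[insertions$chrom == ch, ]
      v <- numeric(max(sub$pos) + 1L)
      v[sub$pos + 1L] <- sub$count
      tracks[[ch]] <- v
    }
  } else {
    tracks <- insertions
  }
  half <- window %/% 2L
  sums <- numeric(window)
  used <- 0L; skipped <- 0L
  for (i in seq_len(nrow(instances))) {
    tr <- tracks[[instances$chrom[i]]]
    if (is.null(tr)) { skipped <- skipped + 1L; next }
    center <- (instances$start[i] + instances$end[i]) %/% 2
    lo <- center - half
    if (lo < 0 || lo + window > length(tr)) { skipped <- skipped + 1L; next }
    sums <- sums + tr[(lo + 1L):(lo + window)]
    used <- used + 1L
  }
  if (skipped > 0) {
    warn(sprintf("Skipped %d windows truncated by track boundaries.", skipped))
  }
  nf <- max(1L, round(flank_frac * window))
  flank_mean <- mean(c(sums[seq_len(nf)], sums[(window - nf + 1L):window]))
  if (flank_mean == 0) {
    abort(sprintf(
      "Undefined footprint normalization: zero flank insertions over %d windows.",
      used),
      class = "motifsyntax_normalization_error")
  }
  out <- tibble(position = seq(-half, half - 1L), insertions = sums,
                normalized = sums / flank_mean)
  class(out) <- c("footprint", class(out))
  attr(out, "n_windows") <- used
  out
}
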