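# Contribution-aware motif instance calling and post-processing: greedy
# matching-pursuit hit calling on contribution tracks, instance-CWM quality
# filtering, and overlap deduplication.

# Pearson correlation of two equal-length vectors; NA when either is
# constant.
.flat_cor <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  n <- length(a)
  va <- sum(a * a) - sa * sa / n
  vb <- sum(b * b) - sb * sb / n
  if (va <= 0 || vb <= 0) return(NA_real_)
  (sum(a * b) - sa * sb / n) / sqrt(va * vb)
}

.motif_cwm_list <- function(motifs) {
  if (is.list(motifs) && !is.data.frame(motifs) &&
      all(vapply(motifs, function(m) {
        inherits(m, "motif") || inherits(m, "trimmed_motif") || is.matrix(m)
      }, logical(1)))) {
    cwms <- map(motifs, .get_cwm)
    labels <- names(motifs) %||% map_chr(motifs, function(m) {
      if (is.matrix(m)) NA_character_ else m$label
    })
    if (any(is.na(labels))) .param_error("Motifs must be named or labelled.")
    setNames(cwms, labels)
  } else {
    .param_error("`motifs` must be a list of motifs, trimmed motifs or matrices.")
  }
}

#' Call motif instances from a contribution track by greedy matching pursuit
#'
#' Scans a 4 x N contribution track (per-base contribution scores projected
#' onto the observed bases, zeros elsewhere) with a set of trimmed motif
#' CWMs. At each iteration the (motif, offset, strand) placement with the
#' highest Pearson correlation between the residual track segment and the
#' CWM is selected; if the correlation reaches `min_similarity` an instance
#' is recorded with that correlation as its `hit_correlation`, the
#' least-squares-scaled CWM is subtracted from the residual, and the scan
#' repeats until no qualifying placement remains.
#'
#' @param track Numeric 4 x N matrix (rows A,C,G,T).
#' @param motifs Named list of trimmed motifs, motifs or 4 x L CWM matrices.
#' @param min_similarity Minimum correlation to record an instance.
#' @param max_hits Maximum number of instances to call.
#' @param chrom Chromosome name attached to the calls.
#' @return A tibble of instances: `chrom`, `start`, `end` (0-based
#'   half-open track coordinates), `strand`, `label`, `hit_correlation`,
#'   `contribution` (summed |track| over the span at selection).
#' @export
greedy_hit_caller <- function(track, motifs, min_similarity = 0.8,
                              max_hits = 100L, chrom = "chr1") {
  .check_matrix4(track, "track")
  cwms <- .motif_cwm_list(motifs)
  if (length(cwms) == 0) .param_error("`motifs` must be nonempty.")
  if (max(vapply(cwms, ncol, integer(1))) > ncol(track)) {
    .param_error("Track is shorter than the longest CWM.")
  }
  # orient both strands once
  scan_set <- list()
  for (lab in names(cwms)) {
    cwm <- cwms[[lab]]
    scan_set[[paste0(lab, "+")]] <- list(label = lab, strand = "+",
                                         cwm = cwm, flat = as.vector(cwm))
    rc <- .rc_matrix(cwm)
    scan_set[[paste0(lab, "-")]] <- list(label = lab, strand = "-",
                                         cwm = rc, flat = as.vector(rc))
  }
  hits <- list()
  residual <- track
  while (length(hits) < max_hits) {
    best <- NULL
    for (sc in scan_set) {
      L <- ncol(sc$cwm)
      for (off in seq_len(ncol(track) - L + 1L)) {
        seg <- residual[, off:(off + L - 1L), drop = FALSE]
        r <- .flat_cor(as.vector(seg), sc$flat)
        if (!is.na(r) && (is.null(best) || r > best$r)) {
          best <- list(r = r, off = off, sc = sc)
        }
      }
    }
    if (is.null(best) || best$r < min_similarity) break
    L <- ncol(best$sc$cwm)
    span <- best$off:(best$off + L - 1L)
    seg <- residual[, span, drop = FALSE]
    hits[[length(hits) + 1L]] <- tibble(
      chrom = chrom, start = best$off - 1L, end = best$off - 1L + L,
      strand = best$sc$strand, label = best$sc$label,
      hit_correlation = best$r, contribution = sum(abs(seg))
    )
    beta <- sum(seg * best$sc$cwm) / sum(best$sc$cwm^2)
    residual[, span] <- seg - beta * best$sc$cwm
  }
  if (length(hits) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), label = character(),
                  hit_correlation = numeric(), contribution = numeric()))
  }
  bind_rows(hits) |> arrange(.data$chrom, .data$start, .data$end)
}

#' Filter motifs by instance-CWM agreement
#'
#' For each motif, averages the contribution-track segments of all its
#' instances (aligned by strand) into an instance-CWM, and drops the motif
#' -- with all of its instances -- when the correlation between the
#' instance-CWM and the input CWM falls below `min_r`. Motifs with zero
#' instances are dropped and flagged separately.
#'
#' @param instances Instance tibble (see [greedy_hit_caller()]).
#' @param motifs Named list of trimmed motifs / CWM matrices.
#' @param tracks Named list of 4 x N contribution tracks keyed by
#'   chromosome, or a single matrix used for all instances.
#' @param min_r Retention threshold on the instance-CWM correlation
#'   (default 0.9).
#' @return The retained instances; the per-motif QC table (columns `label`,
#'   `n_instances`, `instance_r`, `dropped`, `reason`) is attached as the
#'   `"motif_qc"` attribute and returned by [motif_qc()].
#' @export
quality_filter <- function(instances, motifs, tracks, min_r = 0.9) {
  cwms <- .motif_cwm_list(motifs)
  if (is.matrix(tracks)) {
    single <- tracks
    get_track <- function(ch) single
  } else {
    get_track <- function(ch) {
      tr <- tracks[[ch]]
      if (is.null(tr)) .param_error(paste0("No track for chromosome ", ch))
      tr
    }
  }
  qc <- map(names(cwms), function(lab) {
    idx <- which(instances$label == lab)
    if (length(idx) == 0) {
      return(tibble(label = lab, n_instances = 0L, instance_r = NA_real_,
                    dropped = TRUE, reason = "no_instances"))
    }
    cwm <- cwms[[lab]]
    acc <- matrix(0, 4L, ncol(cwm))
    for (i in idx) {
      tr <- get_track(instances$chrom[i])
      seg <- tr[, (instances$start[i] + 1L):instances$end[i], drop = FALSE]
      if (identical(instances$strand[i], "-")) seg <- .rc_matrix(seg)
      acc <- acc + seg
    }
    inst_cwm <- acc / length(idx)
    r <- .flat_cor(as.vector(inst_cwm), as.vector(cwm))
    dropped <- is.na(r) || r < min_r
    tibble(label = lab, n_instances = length(idx), instance_r = r,
           dropped = dropped,
           reason = if (dropped) "low_instance_cwm_correlation" else NA_character_)
  }) |> bind_rows()
  keep <- qc$label[!qc$dropped]
  out <- instances |> filter(.data$label %in% keep)
  attr(out, "motif_qc") <- qc
  out
}

#' Per-motif QC table from [quality_filter()]
#' @param x Output of [quality_filter()].
#' @return The motif QC tibble.
#' @export
motif_qc <- function(x) attr(x, "motif_qc")

#' Deduplicate overlapping same-motif instances
#'
#' Among instances with the same label on the same chromosome whose spans
#' overlap by more than `max_overlap` bp, only the instance with the
#' highest `hit_correlation` is retained (ties: leftmost start, then first
#' in input). Instances of different motifs never conflict; overlap of
#' exactly `max_overlap` bp is allowed.
#'
#' @param instances Instance tibble.
#' @param max_overlap Largest tolerated overlap in bp (default 3).
#' @return The retained instances, sorted by (chrom, start, end).
#' @export
dedup_overlaps <- function(instances, max_overlap = 3L) {
  if (nrow(instances) == 0) return(instances)
  ord <- order(-instances$hit_correlation, instances$start, instances$end,
               seq_len(nrow(instances)))
  keep <- logical(nrow(instances))
  kept_idx <- list()
  for (i in ord) {
    key <- paste(instances$chrom[i], instances$label[i], sep = "\r")
    prior <- kept_idx[[key]]
    conflict <- FALSE
    for (j in prior) {
      ov <- min(instances$end[i], instances$end[j]) -
        max(instances$start[i], instances$start[j])
      if (ov > max_overlap) { conflict <- TRUE; break }
    }
    if (!conflict) {
      keep[i] <- TRUE
      kept_idx[[key]] <- c(prior, i)
    }
  }
  instances[keep, , drop = FALSE] |>
    arrange(.data$chrom, .data$start, .data$end)
}
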