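# Motif matrix representations and deterministic transformations:
# contribution weight matrices (CWMs), position probability matrices (PPMs),
# flank trimming, consensus extraction, reverse complement and similarity.

#' Construct a motif
#'
#' A motif couples a contribution weight matrix (CWM) -- the mean per-base
#' model-attribution score across the seqlets supporting the motif -- with a
#' position probability matrix (PPM) of base frequencies, a polarity (whether
#' the motif increases or decreases predicted accessibility) and the number of
#' supporting seqlets. Matrices are 4 x L with rows in A, C, G, T order.
#'
#' @param label Character identifier.
#' @param cwm Numeric 4 x L matrix of per-base contribution scores.
#' @param ppm Optional numeric 4 x L matrix of per-position base
#'   probabilities; columns must sum to 1 within 1e-6.
#' @param polarity `"positive"` or `"negative"`: the sign of the motif's
#'   aggregate contribution to predicted accessibility.
#' @param n_seqlets Non-negative count of supporting seqlets.
#' @return An object of class `"motif"`.
#' @examples
#' cwm <- matrix(c(0.5, 0, 0, 0,  0, 0.4, 0, 0,  0, 0, 0.6, 0), nrow = 4)
#' m <- motif("example", cwm)
#' @export
motif <- function(label, cwm, ppm = NULL,
                  polarity = c("positive", "negative"), n_seqlets = 0L) {
  polarity <- match.arg(polarity)
  .check_matrix4(cwm, "cwm")
  if (ncol(cwm) < 3L) {
    .param_error("Motif matrices must have at least 3 columns.")
  }
  rownames(cwm) <- .BASES
  if (!is.null(ppm)) {
    .check_matrix4(ppm, "ppm")
    if (!identical(dim(ppm), dim(cwm))) {
      .param_error("`ppm` and `cwm` must have identical dimensions.")
    }
    if (any(ppm < 0) || any(ppm > 1)) {
      .param_error("`ppm` entries must lie in [0, 1].")
    }
    if (any(abs(colSums(ppm) - 1) > 1e-6)) {
      .param_error("Each `ppm` column must sum to 1 within 1e-6.")
    }
    rownames(ppm) <- .BASES
  }
  if (length(n_seqlets) != 1L || is.na(n_seqlets) || n_seqlets < 0) {
    .param_error("`n_seqlets` must be a single non-negative number.")
  }
  structure(
    list(label = as.character(label), polarity = polarity,
         cwm = cwm, ppm = ppm, n_seqlets = as.integer(n_seqlets)),
    class = "motif"
  )
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif> %s (%s), width %d, %d seqlets\n",
              x$label, x$polarity, ncol(x$cwm), x$n_seqlets))
  invisible(x)
}

#' @export
print.trimmed_motif <- function(x, ...) {
  cat(sprintf("<trimmed motif> %s (%s), width %d, offset %d, consensus %s\n",
              x$label, x$polarity, ncol(x$cwm), x$offset, x$consensus))
  invisible(x)
}

.get_cwm <- function(x, arg = "x") {
  if (inherits(x, "motif") || inherits(x, "trimmed_motif")) return(x$cwm)
  .check_matrix4(x, arg)
  x
}

#' Trim uninformative motif flanks
#'
#' Removes flanking positions whose total absolute contribution (summed over
#' the four bases) falls below `frac` of the maximum total contribution among
#' all positions. The retained span runs from the first to the last passing
#' position, so trimming is contiguous and interior low-contribution columns
#' are kept. Absolute values are used so negative-polarity motifs trim under
#' the same rule.
#'
#' @param x A [motif()] (or a bare 4 x L CWM matrix).
#' @param frac Trimming threshold as a fraction of the maximum per-position
#'   total contribution, in (0, 1). Default 0.3.
#' @return An object of class `"trimmed_motif"` carrying the sliced `cwm`
#'   (and `ppm` when present), the 0-based `offset` of the retained span in
#'   the parent, and the consensus sequence of the trimmed motif.
#' @examples
#' cwm <- matrix(0, 4, 5); cwm[1, ] <- c(0.05, 0.5, 0.2, 1.0, 0.02)
#' trim_cwm(motif("ex", cwm))  # retains positions 2..4
#' @export
trim_cwm <- function(x, frac = 0.3) {
  if (length(frac) != 1L || !is.finite(frac) || frac <= 0 || frac >= 1) {
    .param_error("`frac` must be a single number in (0, 1).")
  }
  if (is.matrix(x)) x <- motif("motif", x)
  if (inherits(x, "trimmed_motif")) {
    x <- structure(
      list(label = x$label, polarity = x$polarity, cwm = x$cwm, ppm = x$ppm,
           n_seqlets = x$n_seqlets),
      class = "motif"
    )
  }
  stopifnot(inherits(x, "motif"))
  totals <- colSums(abs(x$cwm))
  if (all(totals == 0)) {
    abort("Cannot trim an all-zero CWM.", class = "motifsyntax_degenerate_motif")
  }
  keep <- which(totals >= frac * max(totals))
  span <- seq(min(keep), max(keep))
  cwm <- x$cwm[, span, drop = FALSE]
  ppm <- if (!is.null(x$ppm)) x$ppm[, span, drop = FALSE]
  out <- structure(
    list(label = x$label, polarity = x$polarity, cwm = cwm, ppm = ppm,
         offset = min(keep) - 1L, parent_length = ncol(x$cwm),
         n_seqlets = x$n_seqlets, consensus = NA_character_),
    class = "trimmed_motif"
  )
  out$consensus <- consensus_sequence(out)
  out
}

#' Consensus sequence of a motif
#'
#' Picks one base per column: the base with the highest contribution score
#' for positive-polarity motifs, and the base with the highest absolute
#' contribution for negative-polarity motifs (whose informative entries are
#' negative). Ties are broken deterministically by base order A < C < G < T.
#'
#' @param x A `"trimmed_motif"`, [motif()] or bare 4 x L matrix.
#' @param polarity Polarity used when `x` is a bare matrix.
#' @return A DNA string with one base per motif column.
#' @export
consensus_sequence <- function(x, polarity = "positive") {
  if (inherits(x, "motif") || inherits(x, "trimmed_motif")) {
    polarity <- x$polarity
    m <- x$cwm
  } else {
    m <- .check_matrix4(x, "x")
  }
  if (ncol(m) == 0L) {
    abort("Cannot take the consensus of an empty matrix.",
          class = "motifsyntax_degenerate_motif")
  }
  score <- if (identical(polarity, "negative")) abs(m) else m
  idx <- apply(score, 2L, which.max)  # which.max breaks ties toward A<C<G<T
  paste(.BASES[idx], collapse = "")
}

#' Reverse complement
#'
#' For DNA strings, the standard reverse complement. For 4 x L matrices (rows
#' A,C,G,T), swaps rows A/T and C/G and reverses the column order. For motif
#' objects, both matrices (and the consensus, for trimmed motifs) are
#' transformed. `reverse_complement()` is an involution.
#'
#' @param x A DNA string vector, 4 x L matrix, [motif()] or trimmed motif.
#' @return An object of the same kind as `x`.
#' @examples
#' reverse_complement("GATAA")  # "TTATC"
#' @export
reverse_complement <- function(x) UseMethod("reverse_complement")

#' @export
reverse_complement.character <- function(x) .rc_string(x)

#' @export
reverse_complement.matrix <- function(x) {
  .check_matrix4(x, "x")
  .rc_matrix(x)
}

#' @export
reverse_complement.motif <- function(x) {
  x$cwm <- .rc_matrix(x$cwm)
  if (!is.null(x$ppm)) x$ppm <- .rc_matrix(x$ppm)
  x
}

#' @export
reverse_complement.trimmed_motif <- function(x) {
  x$cwm <- .rc_matrix(x$cwm)
  if (!is.null(x$ppm)) x$ppm <- .rc_matrix(x$ppm)
  x$consensus <- .rc_string(x$consensus)
  if (!is.null(x$parent_length)) {
    x$offset <- x$parent_length - x$offset - ncol(x$cwm)
  }
  x
}

#' Convert a position probability matrix to a position frequency matrix
#'
#' Multiplies the PPM entrywise by the total number of supporting seqlets, so
#' each column sums to `n_seqlets`.
#'
#' @param ppm Numeric 4 x L probability matrix (columns sum to 1).
#' @param n_seqlets Non-negative seqlet count.
#' @return A 4 x L count matrix.
#' @export
ppm_to_pfm <- function(ppm, n_seqlets) {
  .check_matrix4(ppm, "ppm")
  if (any(abs(colSums(ppm) - 1) > 1e-6)) {
    .param_error("Each `ppm` column must sum to 1 within 1e-6.")
  }
  if (length(n_seqlets) != 1L || is.na(n_seqlets) || n_seqlets < 0) {
    .param_error("`n_seqlets` must be a single non-negative number.")
  }
  ppm * n_seqlets
}

#' Best-alignment similarity between two motif matrices
#'
#' Maximum Pearson correlation between the flattened entries of two 4 x L
#' matrices over all ungapped column offsets with at least 50% overlap of the
#' shorter matrix (entries outside the overlap are zero-padded), optionally
#' also scanning the reverse complement of `b`. Matrices without any
#' variation are flagged degenerate and given similarity 0.
#'
#' @param a,b 4 x L matrices, motifs or trimmed motifs.
#' @param allow_rc Also consider the reverse complement of `b`.
#' @return A one-row tibble with columns `correlation`, `offset` (columns of
#'   `b`'s start relative to `a`'s start at the best alignment), `strand`
#'   (`"+"` or `"-"`), and `degenerate`.
#' @export
cwm_similarity <- function(a, b, allow_rc = TRUE) {
  ma <- .get_cwm(a, "a")
  mb <- .get_cwm(b, "b")
  if (ncol(ma) < 1L || ncol(mb) < 1L) {
    .param_error("Both matrices must have at least one column.")
  }
  if (sd(ma) == 0 || sd(mb) == 0) {
    return(tibble(correlation = 0, offset = 0L, strand = "+",
                  degenerate = TRUE))
  }
  best <- list(r = -Inf, offset = 0L, strand = "+")
  strands <- if (isTRUE(allow_rc)) c("+", "-") else "+"
  for (strand in strands) {
    m2 <- if (strand == "-") .rc_matrix(mb) else mb
    res <- .best_offset_cor(ma, m2)
    if (!is.null(res) && res$r > best$r) {
      best <- list(r = res$r, offset = res$offset, strand = strand)
    }
  }
  if (!is.finite(best$r)) {
    return(tibble(correlation = 0, offset = 0L, strand = "+",
                  degenerate = TRUE))
  }
  tibble(correlation = best$r, offset = as.integer(best$offset),
         strand = best$strand, degenerate = FALSE)
}

# Max Pearson correlation over ungapped offsets with >= 50% overlap of the
# shorter matrix; columns outside either matrix are zero-padded.
.best_offset_cor <- function(ma, mb) {
  la <- ncol(ma); lb <- ncol(mb)
  min_ov <- ceiling(0.5 * min(la, lb))
  best <- NULL
  for (d in seq(-(lb - min_ov), la - min_ov)) {
    lo <- min(0L, d)
    hi <- max(la, d + lb)
    width <- hi - lo
    va <- matrix(0, 4L, width)
    vb <- matrix(0, 4L, width)
    va[, (1L - lo):(la - lo)] <- ma
    vb[, (d - lo + 1L):(d - lo + lb)] <- mb
    if (sd(va) == 0 || sd(vb) == 0) next
    r <- cor(as.vector(va), as.vector(vb))
    if (is.null(best) || r > best$r) best <- list(r = r, offset = d)
  }
  best
}
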