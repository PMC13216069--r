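# Arrangement enumeration and sequence editing: an "arrangement" is a
# combination of the relative orientation of two motif blocks and their
# edge-to-edge spacing (gap). Orientations are canonicalized modulo reverse
# complementation of the whole insert, which leaves 3 unique codes for a pair
# of identical motifs (tandem, head_to_head, tail_to_tail) and 4 for a
# distinct pair (A+B+, A+B-, A-B+, A-B-).

.SAME_CODES <- c("tandem", "head_to_head", "tail_to_tail")
.DISTINCT_CODES <- c("A+B+", "A+B-", "A-B+", "A-B-")

# Canonical arrangement code for two matched blocks ordered left to right.
# `first_is_a`: whether the left block is motif A; s1/s2: strands of the left
# and right blocks. Reverse-complementing the whole insert maps
# (first = B, s1, s2) to (first = A, -s2, -s1).
.canonical_code <- function(first_is_a, s1, s2, same) {
  if (same) {
    if (s1 == s2) return("tandem")
    if (s1 == "-") return("head_to_head")
    return("tail_to_tail")
  }
  flip <- function(s) if (s == "+") "-" else "+"
  if (first_is_a) paste0("A", s1, "B", s2)
  else paste0("A", flip(s2), "B", flip(s1))
}

# Left and right sequence blocks realizing an orientation code.
.oriented_blocks <- function(seq_a, seq_b, code) {
  switch(code,
    tandem = c(seq_a, seq_a),
    head_to_head = c(.rc_string(seq_a), seq_a),
    tail_to_tail = c(seq_a, .rc_string(seq_a)),
    "A+B+" = c(seq_a, seq_b),
    "A+B-" = c(seq_a, .rc_string(seq_b)),
    "A-B+" = c(.rc_string(seq_a), seq_b),
    "A-B-" = c(.rc_string(seq_a), .rc_string(seq_b)),
    .param_error(paste0("Unknown orientation code: ", code))
  )
}

# Canonical ordering used for deterministic iteration and tie-breaking.
.orientation_rank <- function(code) {
  match(code, c(.SAME_CODES, .DISTINCT_CODES))
}

#' Enumerate unique pair orientations
#'
#' All 2 (order) x 2 x 2 (strand) combinations of two motif sequences,
#' canonicalized modulo reverse complementation of the whole insert: 3 unique
#' orientations for a pair of identical motifs, 4 for a distinct pair. With
#' `dedup = TRUE`, codes whose oriented inserts are string-identical (as
#' happens for palindromic sequences) are collapsed.
#'
#' @param seq_a,seq_b Consensus DNA strings.
#' @param dedup Collapse orientations whose edited inserts coincide.
#' @return Character vector of orientation codes.
#' @examples
#' enumerate_orientations("GATAA", "GATAA")   # 3 codes
#' enumerate_orientations("GATAA", "CACGTG")  # 4 codes
#' @export
enumerate_orientations <- function(seq_a, seq_b, dedup = FALSE) {
  .check_dna(seq_a, "seq_a"); .check_dna(seq_b, "seq_b")
  codes <- if (identical(seq_a, seq_b)) .SAME_CODES else .DISTINCT_CODES
  if (!isTRUE(dedup)) return(codes)
  keys <- vapply(codes, function(code) {
    bl <- .oriented_blocks(seq_a, seq_b, code)
    fwd <- paste(bl, collapse = "|")
    rev <- paste(.rc_string(bl[2L]), .rc_string(bl[1L]), sep = "|")
    min(fwd, rev)
  }, character(1))
  codes[!duplicated(keys)]
}

#' Substitute motif blocks into background sequences
#'
#' Single-motif mode replaces the central bases of each background with
#' `seq_a`. Pair mode places the two oriented blocks symmetrically about the
#' window center, `gap` bases apart edge to edge; the gap bases retain the
#' original background sequence, so each insertion is an independent
#' substitution.
#'
#' @param background Character vector of equal-length background sequences.
#' @param seq_a,seq_b Motif consensus sequences (`seq_b = NULL` for
#'   single-motif mode).
#' @param orientation Orientation code from [enumerate_orientations()]
#'   (pair mode).
#' @param gap Edge-to-edge spacing in bp (pair mode).
#' @return Character vector of edited sequences, same length and widths as
#'   `background`.
#' @export
build_edited_sequence <- function(background, seq_a, seq_b = NULL,
                                  orientation = NULL, gap = 0L) {
  background <- as.character(background)  # drop library attributes
  .check_dna(background, "background")
  .check_dna(seq_a, "seq_a")
  widths <- unique(nchar(background))
  if (length(widths) != 1L) {
    .param_error("All background sequences must have equal length.")
  }
  L <- widths
  if (is.null(seq_b)) {
    la <- nchar(seq_a)
    if (la > L) {
      abort("Inserted motif is longer than the background window.",
            class = "motifsyntax_span_error")
    }
    s0 <- (L - la) %/% 2L           # 0-based start
    out <- background
    substr(out, s0 + 1L, s0 + la) <- seq_a
    return(out)
  }
  .check_dna(seq_b, "seq_b")
  if (is.null(orientation)) .param_error("Pair mode needs an `orientation`.")
  if (length(gap) != 1L || gap < 0) .param_error("`gap` must be >= 0.")
  bl <- .oriented_blocks(seq_a, seq_b, orientation)
  l1 <- nchar(bl[1L]); l2 <- nchar(bl[2L])
  span <- l1 + gap + l2
  if (span > L) {
    abort(sprintf(
      "Arrangement span %d bp exceeds the %d bp background window.", span, L),
      class = "motifsyntax_span_error")
  }
  s0 <- (L - span) %/% 2L
  out <- background
  substr(out, s0 + 1L, s0 + l1) <- bl[1L]
  substr(out, s0 + l1 + gap + 1L, s0 + span) <- bl[2L]
  out
}
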