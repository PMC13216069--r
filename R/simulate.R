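# Seeded simulators: GC-matched background sequence libraries, paired-end
# fragments under the 9-bp Tn5 duplication model, and fine-mapped
# variant-gene (eQTL) tables with signed effects concentrated in motif
# instances.

.random_dna <- function(n, length, gc) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(.BASES, length, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
}

.gc_fraction <- function(x) {
  (nchar(gsub("[AT]", "", x))) / nchar(x)
}

#' Generate a GC-matched background sequence library
#'
#' Seeded rejection sampling of random sequences whose GC fraction falls
#' within `tolerance` of `gc_target` and which contain no forbidden
#' consensus sequence on either strand -- emulating non-accessible,
#' GC-matched background regions that carry no planted motif.
#'
#' @param n Number of sequences (default 100).
#' @param length Sequence length in bp (default 2114, a typical model input
#'   window).
#' @param gc_target Target GC fraction in (0, 1).
#' @param tolerance Allowed deviation of each sequence's GC fraction.
#' @param forbidden Character vector of consensus sequences that must not
#'   occur (reverse complements are excluded automatically).
#' @param seed Integer seed.
#' @param max_tries Rejection budget per sequence.
#' @return A character vector of class `"background_library"` with
#'   attributes `gc_target`, `tolerance` and `seed`.
#' @export
make_background_library <- function(n = 100L, length = 2114L,
                                    gc_target = 0.5, tolerance = 0.02,
                                    forbidden = character(), seed = 1L,
                                    max_tries = 500L) {
  if (gc_target <= 0 || gc_target >= 1) .param_error("`gc_target` must be in (0,1).")
  if (n < 1) .param_error("`n` must be at least 1.")
  if (length(forbidden) > 0) .check_dna(forbidden, "forbidden")
  pats <- unique(c(forbidden, if (length(forbidden)) .rc_string(forbidden)))
  out <- with_seed(seed, {
    vapply(seq_len(n), function(i) {
      gc_fail <- 0L; motif_fail <- 0L
      for (try in seq_len(max_tries)) {
        s <- .random_dna(1L, length, gc_target)
        if (abs(.gc_fraction(s) - gc_target) > tolerance) {
          gc_fail <- gc_fail + 1L
          next
        }
        if (length(pats) &&
            any(vapply(pats, function(p) grepl(p, s, fixed = TRUE),
                       logical(1)))) {
          motif_fail <- motif_fail + 1L
          next
        }
        return(s)
      }
      worst <- if (gc_fail >= motif_fail) "GC-content" else "motif-exclusion"
      abort(sprintf(
        "Could not satisfy the %s constraint after %d tries per sequence.",
        worst, max_tries),
        class = "motifsyntax_constraint_error")
    }, character(1))
  })
  structure(out, gc_target = gc_target, tolerance = tolerance, seed = seed,
            class = c("background_library", "character"))
}

#' Simulate fragments from Tn5 transposition events
#'
#' Each transposition event at center `c` creates two insertions 9 bp apart
#' counted as the inclusive duplicated span: the plus-strand insertion at
#' `c - 4` and the minus-strand insertion at `c + 4` (0-based coordinates of
#' the first duplicated base on each strand). Consecutive events on the same
#' chromosome and barcode are chained into fragments running from one
#' event's plus insertion to the next event's minus insertion, so interior
#' events are shared by two fragments -- the property exploited by
#' [tn5_mate_consistency()]. Fragments are reported 0-based end-exclusive.
#'
#' @param events Tibble with columns `chrom`, `center` (0-based bp, at least
#'   4) and optionally `barcode`.
#' @return A list with `fragments` (tibble `chrom`, `start`, `end`,
#'   `barcode`, `count`, `start_event`, `end_event`) and `insertions`
#'   (tibble `chrom`, `pos`, `count` incremented at every reported fragment
#'   endpoint insertion).
#' @examples
#' simulate_fragments(tibble::tibble(chrom = "chr1", center = c(100, 300)))
#' @export
simulate_fragments <- function(events) {
  if (is.null(events) || nrow(events) == 0) {
    empty <- tibble(chrom = character(), start = integer(), end = integer(),
                    barcode = character(), count = integer(),
                    start_event = character(), end_event = character())
    return(list(fragments = empty,
                insertions = tibble(chrom = character(), pos = integer(),
                                    count = integer())))
  }
  stopifnot(all(c("chrom", "center") %in% names(events)))
  if (any(events$center < 4)) {
    .param_error("Event centers must be at least 4 bp from the chromosome start.")
  }
  if (!"barcode" %in% names(events)) events$barcode <- "BC1"
  dup <- duplicated(events[c("chrom", "center", "barcode")])
  if (any(dup)) {
    warn(sprintf("Skipped %d colliding events at duplicated centers.",
                 sum(dup)))
    events <- events[!dup, , drop = FALSE]
  }
  events <- events |>
    mutate(event_id = paste(.data$chrom, .data$center, .data$barcode,
                            sep = ":")) |>
    arrange(.data$chrom, .data$barcode, .data$center)
  frags <- events |>
    group_by(.data$chrom, .data$barcode) |>
    dplyr::reframe(
      start = head(.data$center, -1L) - 4L,
      end = tail(.data$center, -1L) + 4L + 1L,
      start_event = head(.data$event_id, -1L),
      end_event = tail(.data$event_id, -1L)
    ) |>
    mutate(count = 1L) |>
    select("chrom", "start", "end", "barcode", "count",
           "start_event", "end_event") |>
    arrange(.data$chrom, .data$start, .data$end)
  ins <- bind_rows(
    tibble(chrom = frags$chrom, pos = frags$start),
    tibble(chrom = frags$chrom, pos = frags$end - 1L)
  ) |>
    group_by(.data$chrom, .data$pos) |>
    summarise(count = n(), .groups = "drop") |>
    arrange(.data$chrom, .data$pos)
  list(fragments = frags, insertions = ins)
}

#' Simulate a fine-mapped variant-gene (eQTL) table
#'
#' Places variants inside motif instances with probability
#' `frac_in_instances` and elsewhere otherwise. A variant inside a
#' positive-polarity motif instance is downregulating (negative allelic fold
#' change) with probability `direction_fidelity`, and a variant inside a
#' negative motif is upregulating with that probability; off-instance
#' variants carry random signs. Posterior inclusion probabilities are drawn
#' from a Beta distribution.
#'
#' @param instances Tibble with columns `chrom`, `start`, `end`, `label`,
#'   `polarity`.
#' @param n_variants Number of variants to simulate.
#' @param frac_in_instances Probability a variant falls inside an instance.
#' @param direction_fidelity Probability an in-instance variant's direction
#'   matches the motif polarity model described above.
#' @param pip_shape1,pip_shape2 Beta distribution parameters for PIPs.
#' @param seed Integer seed.
#' @return A tibble with columns `variant_id`, `chrom`, `pos` (0-based),
#'   `gene`, `pip`, `afc` (signed log2 allelic fold change; positive =
#'   upregulating).
#' @export
simulate_eqtl_table <- function(instances, n_variants,
                                frac_in_instances = 0.5,
                                direction_fidelity = 0.9,
                                pip_shape1 = 1, pip_shape2 = 3,
                                seed = 1L) {
  if (frac_in_instances < 0 || frac_in_instances > 1 ||
      direction_fidelity < 0 || direction_fidelity > 1) {
    .param_error("`frac_in_instances` and `direction_fidelity` must be in [0,1].")
  }
  no_inst <- is.null(instances) || nrow(instances) == 0
  if (no_inst && frac_in_instances > 0) {
    .param_error("No instances supplied but `frac_in_instances` > 0.")
  }
  with_seed(seed, {
    chroms <- if (no_inst) "chr1" else unique(instances$chrom)
    extent <- if (no_inst) {
      setNames(rep(100000L, length(chroms)), chroms)
    } else {
      vapply(chroms, function(ch) {
        max(instances$end[instances$chrom == ch]) + 5000L
      }, integer(1))
    }
    in_any_instance <- function(ch, pos) {
      if (no_inst) return(FALSE)
      any(instances$chrom == ch & instances$start <= pos &
            pos < instances$end)
    }
    rows <- map(seq_len(n_variants), function(i) {
      inside <- runif(1) < frac_in_instances
      if (inside) {
        j <- sample.int(nrow(instances), 1L)
        ch <- instances$chrom[j]
        pos <- if (instances$end[j] - instances$start[j] == 1L) {
          instances$start[j]
        } else {
          sample(instances$start[j]:(instances$end[j] - 1L), 1L)
        }
        faithful <- runif(1) < direction_fidelity
        positive <- identical(instances$polarity[j], "positive")
        down <- if (positive) faithful else !faithful
      } else {
        ch <- sample(chroms, 1L)
        repeat {
          pos <- sample.int(extent[[ch]], 1L) - 1L
          if (!in_any_instance(ch, pos)) break
        }
        down <- runif(1) < 0.5
      }
      mag <- abs(rnorm(1, 0.5, 0.2)) + 0.05
      tibble(variant_id = sprintf("var%05d", i), chrom = ch,
             pos = as.integer(pos),
             gene = paste0("gene", sample.int(max(3L, n_variants %/% 5L), 1L)),
             pip = rbeta(1, pip_shape1, pip_shape2),
             afc = if (down) -mag else mag)
    })
    bind_rows(rows)
  })
}
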