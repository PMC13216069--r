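# Readers and writers for the interchange formats (BED, the motif matrix
# block format, MEME minimal, fragment and variant TSVs, run configuration)
# and the Tn5 insertion offset correction with mate-consistency checking.
# All genomic coordinates are 0-based half-open throughout.

.parse_error <- function(path, line, msg) {
  abort(sprintf("%s:%d: %s", path, line, msg),
        class = "motifsyntax_parse_error")
}

#' Read / write BED intervals
#'
#' BED3/BED6+ with 0-based half-open coordinates. Extra columns beyond the
#' standard six are preserved. Output is sorted by (chrom, start, end);
#' malformed lines (start >= end, negative coordinates, too few columns)
#' raise a parse error naming the line.
#'
#' @param path File path.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand` and any extra columns.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3L)) {
    .parse_error(path, which(ncols < 3L)[1], "fewer than 3 columns")
  }
  nc <- min(ncols)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    .parse_error(path, bad[1], "invalid interval (need 0 <= start < end)")
  }
  out <- tibble(chrom = vapply(fields, `[[`, "", 1L),
                start = start, end = end)
  std <- c("name", "score", "strand")
  for (k in seq_len(min(nc, 6L) - 3L)) {
    out[[std[k]]] <- vapply(fields, `[[`, "", 3L + k)
  }
  if ("score" %in% names(out)) {
    out$score <- suppressWarnings(as.numeric(out$score))
  }
  for (k in seq_len(max(nc - 6L, 0L))) {
    col <- vapply(fields, `[[`, "", 6L + k)
    num <- suppressWarnings(as.numeric(col))
    out[[paste0("extra", k)]] <- if (all(!is.na(num))) num else col
  }
  arrange(out, .data$chrom, .data$start, .data$end)
}

#' @rdname read_bed
#' @param x Interval tibble (`chrom`, `start`, `end`, optional `name`,
#'   `score`, `strand` and extras).
#' @export
write_bed <- function(x, path) {
  x <- arrange(x, .data$chrom, .data$start, .data$end)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  extras <- setdiff(names(x), cols)
  readr::write_tsv(x[, c(cols, extras)], path, col_names = FALSE)
  invisible(path)
}

#' Write motif instances as BED6+
#'
#' Name is the motif label, score is `1000 * hit_correlation` clamped to
#' `[0, 1000]`, and `hit_correlation` and `contribution` ride along as
#' extra columns.
#'
#' @param instances Instance tibble.
#' @param path File path.
#' @export
write_instances_bed <- function(instances, path) {
  out <- tibble(
    chrom = instances$chrom, start = instances$start, end = instances$end,
    name = instances$label,
    score = pmin(pmax(round(1000 * instances$hit_correlation), 0), 1000),
    strand = instances$strand,
    hit_correlation = instances$hit_correlation,
    contribution = instances$contribution
  )
  write_bed(out, path)
}

# ---- motif matrix block format --------------------------------------------

#' Read / write motifs in the block text format
#'
#' Per motif and matrix kind, a header line
#' `>label polarity=+|- n_seqlets=<int> kind=CWM|PPM` followed by L rows of
#' 4 whitespace-separated numbers in A,C,G,T order, with a blank line
#' between blocks. CWM and PPM blocks sharing a label are combined into one
#' [motif()]. PPM validation (column sums within 1e-3 of 1) is applied on
#' read; a block without `n_seqlets` defaults to 0 with a warning.
#'
#' @param path File path.
#' @return A named list of [motif()] objects.
#' @export
read_motifs <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0) {
    abort(paste0("No motif blocks found in ", path),
          class = "motifsyntax_parse_error")
  }
  blocks <- list()
  bounds <- c(hdr_idx, length(lines) + 1L)
  for (b in seq_along(hdr_idx)) {
    hline <- lines[hdr_idx[b]]
    toks <- strsplit(sub("^>", "", hline), "\\s+")[[1]]
    label <- toks[1]
    get_field <- function(key) {
      hit <- grep(paste0("^", key, "="), toks, value = TRUE)
      if (length(hit) == 0) NA_character_ else sub(paste0(key, "="), "", hit[1])
    }
    polarity <- switch(get_field("polarity"),
                       "+" = "positive", "-" = "negative",
                       .parse_error(path, hdr_idx[b], "missing polarity=+|-"))
    kind <- get_field("kind")
    if (!kind %in% c("CWM", "PPM")) {
      .parse_error(path, hdr_idx[b], "missing kind=CWM|PPM")
    }
    ns <- get_field("n_seqlets")
    if (is.na(ns)) {
      warn(sprintf("Motif %s has no n_seqlets field; defaulting to 0.", label))
      ns <- "0"
    }
    body <- lines[(hdr_idx[b] + 1L):(bounds[b + 1L] - 1L)]
    body <- body[nzchar(trimws(body))]
    rows <- strsplit(trimws(body), "\\s+")
    if (any(lengths(rows) != 4L)) {
      .parse_error(path, hdr_idx[b] + which(lengths(rows) != 4L)[1],
                   sprintf("motif %s: expected 4 columns per row", label))
    }
    mat <- t(vapply(rows, function(r) as.numeric(r), numeric(4)))
    mat <- t(mat)  # 4 x L, rows A,C,G,T
    rownames(mat) <- .BASES
    if (kind == "PPM" && any(abs(colSums(mat) - 1) > 1e-3)) {
      abort(sprintf("PPM columns of motif %s do not sum to 1.", label),
            class = "motifsyntax_parse_error")
    }
    blocks[[length(blocks) + 1L]] <- list(label = label, polarity = polarity,
                                          kind = kind, mat = mat,
                                          n_seqlets = as.integer(ns))
  }
  labs <- unique(vapply(blocks, `[[`, "", "label"))
  out <- list()
  for (lab in labs) {
    mine <- blocks[vapply(blocks, function(b) b$label == lab, logical(1))]
    cwm <- NULL; ppm <- NULL
    for (b in mine) {
      if (b$kind == "CWM") cwm <- b$mat else ppm <- b$mat
    }
    if (is.null(cwm)) {
      # PPM-only blocks: carry the PPM as a zero-centred stand-in CWM is
      # not meaningful, so require a CWM block.
      abort(sprintf("Motif %s has no CWM block.", lab),
            class = "motifsyntax_parse_error")
    }
    out[[lab]] <- motif(lab, cwm, ppm, polarity = mine[[1]]$polarity,
                        n_seqlets = mine[[1]]$n_seqlets)
  }
  out
}

#' @rdname read_motifs
#' @param motifs Named list of [motif()] objects.
#' @export
write_motifs <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt_block <- function(m, kind, mat) {
    pol <- if (m$polarity == "positive") "+" else "-"
    c(sprintf(">%s polarity=%s n_seqlets=%d kind=%s",
              m$label, pol, m$n_seqlets, kind),
      apply(mat, 2L, function(col) paste(sprintf("%.6f", col), collapse = " ")))
  }
  for (m in motifs) {
    writeLines(fmt_block(m, "CWM", m$cwm), con)
    writeLines("", con)
    if (!is.null(m$ppm)) {
      writeLines(fmt_block(m, "PPM", m$ppm), con)
      writeLines("", con)
    }
  }
  invisible(path)
}

#' Read / write PPMs in MEME minimal format
#'
#' @param path File path.
#' @return For `read_meme()`, a named list with elements `ppm` (4 x L
#'   matrix) and `nsites` per motif.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  idx <- grep("^MOTIF ", lines)
  out <- list()
  for (i in seq_along(idx)) {
    label <- strsplit(lines[idx[i]], "\\s+")[[1]][2]
    hdr <- grep("^letter-probability matrix", lines)
    hdr <- hdr[hdr > idx[i]][1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    nsites <- if (grepl("nsites=", lines[hdr])) {
      as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", lines[hdr]))
    } else 0L
    rows <- lines[(hdr + 1L):(hdr + w)]
    mat <- t(vapply(strsplit(trimws(rows), "\\s+"),
                    function(r) as.numeric(r), numeric(4)))
    ppm <- t(mat)
    rownames(ppm) <- .BASES
    out[[label]] <- list(ppm = ppm, nsites = nsites)
  }
  out
}

#' @rdname read_meme
#' @param ppms Named list of 4 x L probability matrices, or of lists with
#'   elements `ppm` and `nsites`.
#' @export
write_meme <- function(ppms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -",
               "", "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (lab in names(ppms)) {
    entry <- ppms[[lab]]
    ppm <- if (is.matrix(entry)) entry else entry$ppm
    nsites <- if (is.matrix(entry)) 0L else entry$nsites %||% 0L
    writeLines(sprintf("MOTIF %s", lab), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      ncol(ppm), nsites), con)
    writeLines(apply(ppm, 2L, function(col) {
      paste(sprintf("%.6f", col), collapse = " ")
    }), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read / write fragment files
#'
#' Tab-separated `chrom`, `start`, `end`, `barcode`, `count` records with
#' 0-based end-exclusive coordinates, the standard plain-text layout of
#' ATAC fragment files.
#'
#' @param path File path.
#' @return A tibble of fragments.
#' @export
read_fragments <- function(path) {
  readr::read_tsv(path,
                  col_names = c("chrom", "start", "end", "barcode", "count"),
                  col_types = "ciici", progress = FALSE)
}

#' @rdname read_fragments
#' @param fragments Fragment tibble.
#' @export
write_fragments <- function(fragments, path) {
  readr::write_tsv(
    fragments[, c("chrom", "start", "end", "barcode", "count")],
    path, col_names = FALSE)
  invisible(path)
}

#' Read / write variant-gene tables
#'
#' TSV with header columns `variant_id`, `chrom`, `pos` (0-based), `gene`,
#' `pip`, `afc`.
#'
#' @param path File path.
#' @return A tibble of variant-gene pairs.
#' @export
read_variants <- function(path) {
  out <- readr::read_tsv(path, col_types = "ccicdd", progress = FALSE)
  stopifnot(all(c("variant_id", "chrom", "pos", "gene", "pip", "afc") %in%
                  names(out)))
  if (any(out$pip < 0 | out$pip > 1)) {
    abort("PIP values must lie in [0, 1].", class = "motifsyntax_parse_error")
  }
  out
}

#' @rdname read_variants
#' @param pairs Variant-gene tibble.
#' @export
write_variants <- function(pairs, path) {
  readr::write_tsv(
    pairs[, c("variant_id", "chrom", "pos", "gene", "pip", "afc")], path)
  invisible(path)
}

#' Read a run configuration
#'
#' A single human-readable YAML document holding the seed, window geometry,
#' marginalization grid, synergy thresholds and shuffle count; unspecified
#' fields take the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- list(
    seed = 1L, window_length = 2114L, profile_length = 1000L, n_folds = 5L,
    gaps = list(from = 0L, to = 200L, by = 1L),
    alpha_adj = 0.001, min_diff = 0.15, z_hard = 4,
    soft_range = c(20L, 150L), n_shuffles = 100000L
  )
  cfg <- utils::modifyList(defaults, raw)
  structure(cfg, class = "run_config")
}

# ---- Tn5 offset correction -------------------------------------------------

.TN5_SCHEMES <- list("+4/-4" = c(plus = 4L, minus = -4L),
                     "+4/-5" = c(plus = 4L, minus = -5L))

#' Tn5 insertion offset correction
#'
#' Expands each fragment into its two insertion records -- the plus-strand
#' insertion at `start` and the minus-strand insertion at `end - 1` (the
#' 0-based position of the first duplicated base on each strand under the
#' end-exclusive fragment convention) -- and applies the per-strand offset
#' scheme. The `+4/-4` scheme maps both insertions of a shared
#' transposition event to one consensus coordinate; the legacy `+4/-5`
#' scheme leaves a 1-bp mismatch.
#'
#' @param fragments Fragment tibble (`chrom`, `start`, `end`, ...,
#'   optionally `start_event` / `end_event` from [simulate_fragments()]).
#' @param scheme `"+4/-4"` (default) or `"+4/-5"`.
#' @return A tibble with one row per fragment endpoint: `chrom`,
#'   `fragment` (input row), `strand`, `insertion` (raw coordinate),
#'   `adjusted`, and `event` when event annotations are present.
#' @export
tn5_offset_correct <- function(fragments, scheme = c("+4/-4", "+4/-5")) {
  if (is.character(scheme) && length(scheme) == 1L &&
      !scheme %in% names(.TN5_SCHEMES)) {
    abort(sprintf("Unknown Tn5 offset scheme %s; supported: %s.", scheme,
                  paste(names(.TN5_SCHEMES), collapse = ", ")),
          class = "motifsyntax_parameter_error")
  }
  scheme <- match.arg(scheme)
  off <- .TN5_SCHEMES[[scheme]]
  n <- nrow(fragments)
  has_events <- all(c("start_event", "end_event") %in% names(fragments))
  plus <- tibble(chrom = fragments$chrom, fragment = seq_len(n),
                 strand = "+", insertion = fragments$start,
                 adjusted = fragments$start + off[["plus"]])
  minus <- tibble(chrom = fragments$chrom, fragment = seq_len(n),
                  strand = "-", insertion = fragments$end - 1L,
                  adjusted = fragments$end - 1L + off[["minus"]])
  if (has_events) {
    plus$event <- fragments$start_event
    minus$event <- fragments$end_event
  }
  bind_rows(plus, minus) |> arrange(.data$fragment, desc(.data$strand))
}

#' Mate consistency of adjusted insertion coordinates
#'
#' For every simulated transposition event shared by two fragments (one
#' fragment ending and the next starting at that event), reports the
#' absolute difference between their offset-adjusted insertion
#' coordinates. Under `+4/-4` the difference is 0 for every event (a
#' consensus insertion site); under the legacy `+4/-5` it is 1 bp.
#'
#' @inheritParams tn5_offset_correct
#' @return A tibble with one row per shared event: `event`,
#'   `plus_adjusted`, `minus_adjusted`, `difference`.
#' @export
tn5_mate_consistency <- function(fragments, scheme = c("+4/-4", "+4/-5")) {
  if (!all(c("start_event", "end_event") %in% names(fragments))) {
    .param_error(
      "`fragments` must carry start_event/end_event annotations (see simulate_fragments()).")
  }
  adj <- tn5_offset_correct(fragments, scheme)
  plus <- adj |> filter(.data$strand == "+") |>
    select(event = "event", plus_adjusted = "adjusted")
  minus <- adj |> filter(.data$strand == "-") |>
    select(event = "event", minus_adjusted = "adjusted")
  dplyr::inner_join(plus, minus, by = "event") |>
    mutate(difference = abs(.data$plus_adjusted - .data$minus_adjusted))
}
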