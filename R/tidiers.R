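# broom-style tidy() and glance() methods for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tidiers
#' @export
tidy.marginal_effects <- function(x, ...) as_tibble(x)

#' Tidiers for motifsyntax result objects
#'
#' `tidy()` returns the per-record table; `glance()` returns a one-row
#' summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @name tidiers
#' @export
glance.marginal_effects <- function(x, ...) {
  tibble(mean_dA = mean(x$dA), sd_dA = sd(x$dA),
         n_sequences = length(unique(x$seq_idx)),
         n_folds = length(unique(x$fold)))
}

#' @rdname tidiers
#' @export
tidy.effect_table <- function(x, ...) .arrangement_summary(x)

#' @rdname tidiers
#' @export
glance.effect_table <- function(x, ...) {
  opt <- optimal_arrangement(x)
  tibble(n_arrangements = nrow(.arrangement_summary(x)),
         n_sequences = length(unique(x$seq_idx)),
         n_folds = length(unique(x$fold)),
         opt_orientation = opt$orientation, opt_gap = opt$gap,
         opt_mean_dJ = opt$mean_dJ, opt_mean_diff = opt$mean_diff)
}

#' @rdname tidiers
#' @export
tidy.synergy_calls <- function(x, ...) {
  out <- as_tibble(x)
  out$classes <- map_chr(out$classes, paste, collapse = ",")
  out
}

#' @rdname tidiers
#' @export
glance.synergy_calls <- function(x, ...) {
  th <- attr(x, "thresholds") %||% synergy_thresholds()
  tibble(n_composites = nrow(x),
         n_synergistic = sum(x$synergistic, na.rm = TRUE),
         n_hard = sum(x$syntax == "hard", na.rm = TRUE),
         n_soft = sum(x$syntax == "soft", na.rm = TRUE),
         n_abstained = sum(x$status == "abstained"),
         alpha_adj = th$alpha_adj, min_diff = th$min_diff,
         z_hard = th$z_hard)
}

#' @rdname tidiers
#' @export
tidy.variant_effect <- function(x, ...) as_tibble(x)

#' @rdname tidiers
#' @export
glance.variant_effect <- function(x, ...) {
  tibble(delta_counts_100bp = mean(x$delta_counts_100bp),
         log2fc_counts = mean(x$log2fc_counts),
         n_folds = nrow(x))
}

#' @rdname tidiers
#' @export
tidy.eqtl_enrichment <- function(x, ...) as_tibble(x)

#' @rdname tidiers
#' @export
glance.eqtl_enrichment <- function(x, ...) {
  tibble(n_tests = nrow(x), n_significant = sum(x$significant),
         n_shuffles = attr(x, "n_shuffles") %||% NA_integer_)
}

#' @rdname tidiers
#' @export
glance.footprint <- function(x, ...) {
  tibble(n_windows = attr(x, "n_windows") %||% NA_integer_,
         min_normalized = min(x$normalized),
         center_normalized = x$normalized[x$position == 0])
}
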