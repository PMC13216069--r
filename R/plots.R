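# ggplot2 visualizations for the package's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_hline geom_vline geom_tile labs facet_wrap theme_bw
#'   scale_fill_gradient2 element_blank theme
#' @export
ggplot2::autoplot

#' Plot a synergy landscape
#'
#' Mean excess of the joint effect over the log-additive expectation
#' (`dJ - dS`) as a function of gap, one line per orientation. A hard-syntax
#' pair shows a sharp spike at one arrangement; a soft-syntax pair shows a
#' smooth decay with distance.
#'
#' @param object An `"effect_table"` from [marginalize_pair()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.effect_table <- function(object, ...) {
  s <- .arrangement_summary(object)
  ggplot(s, aes(x = .data$gap, y = .data$mean_diff,
                colour = .data$orientation)) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    geom_line() +
    labs(x = "Gap between motifs (bp)",
         y = expression(Delta[J] - Delta[S] ~ "(log counts)"),
         colour = "Orientation") +
    theme_bw()
}

#' Plot a batch of synergy calls
#'
#' Mean `dJ - dS` at the optimal arrangement against the BH-adjusted
#' p-value, coloured by syntax class, with the decision thresholds drawn.
#'
#' @param object A `"synergy_calls"` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synergy_calls <- function(object, ...) {
  th <- attr(object, "thresholds") %||% synergy_thresholds()
  ggplot(object, aes(x = .data$mean_diff, y = -log10(.data$p_adj),
                     colour = .data$syntax)) +
    geom_vline(xintercept = th$min_diff, linetype = "dashed",
               colour = "grey50") +
    geom_hline(yintercept = -log10(th$alpha_adj), linetype = "dashed",
               colour = "grey50") +
    geom_point() +
    labs(x = expression("Mean" ~ Delta[J] - Delta[S] ~ "at optimum"),
         y = expression(-log[10] ~ "adjusted" ~ italic(P)),
         colour = "Syntax") +
    theme_bw()
}

#' Plot a footprint metaplot
#'
#' @param object A `"footprint"` tibble from [footprint_metaplot()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.footprint <- function(object, ...) {
  ggplot(object, aes(x = .data$position, y = .data$normalized)) +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    geom_line() +
    labs(x = "Position relative to motif center (bp)",
         y = "Normalized Tn5 insertions") +
    theme_bw()
}

#' Plot eQTL enrichment results
#'
#' Enrichment score per motif and variant direction; significant
#' motif-direction pairs are emphasized.
#'
#' @param object An `"eqtl_enrichment"` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eqtl_enrichment <- function(object, ...) {
  ggplot(object, aes(x = .data$label, y = .data$enrichment,
                     fill = .data$direction, alpha = .data$significant)) +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    geom_col(position = "dodge") +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.35, `TRUE` = 1),
                                guide = "none") +
    labs(x = NULL, y = "Enrichment (observed / mean shuffled)",
         fill = "Variant direction") +
    theme_bw() +
    theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a motif matrix
#'
#' Per-position, per-base contribution (or probability) values as a tile
#' map -- a compact alternative to a sequence logo.
#'
#' @param x A [motif()], trimmed motif or 4 x L matrix.
#' @param which `"cwm"` or `"ppm"` for motif objects.
#' @return A ggplot object.
#' @export
plot_motif_matrix <- function(x, which = c("cwm", "ppm")) {
  which <- match.arg(which)
  m <- if (is.matrix(x)) x else x[[which]]
  if (is.null(m)) .param_error(paste0("Motif has no ", toupper(which), "."))
  df <- tibble(
    base = factor(rep(rownames(m) %||% .BASES, ncol(m)), levels = rev(.BASES)),
    position = rep(seq_len(ncol(m)), each = 4L),
    value = as.vector(m)
  )
  ggplot(df, aes(x = .data$position, y = .data$base, fill = .data$value)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    labs(x = "Position", y = NULL, fill = "Score") +
    theme_bw() +
    theme(panel.grid = element_blank())
}
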