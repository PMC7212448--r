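# ggplot2 views of the main result types. Each returns a ggplot object the
# caller can restyle.

#' Bar chart of subtype PSM percentages
#'
#' @param fractions Output of [subtype_psm_fractions()].
#' @return A ggplot.
#' @export
plot_subtype_fractions <- function(fractions) {
  x <- dplyr::filter(as_tibble(fractions), !is.na(.data$pct))
  ggplot(x, aes(x = .data$subtype, y = .data$pct)) +
    geom_col(fill = "steelblue") +
    geom_text(aes(label = sprintf("%.1f%%", .data$pct)), vjust = -0.3,
              size = 3) +
    labs(x = NULL, y = "PSM percentage",
         title = "Glycan subtype PSM percentages") +
    theme_minimal()
}

#' Bar chart of glycan feature distributions
#'
#' @param dist Output of [glycan_feature_distribution()].
#' @return A ggplot faceted by feature family.
#' @export
plot_feature_distribution <- function(dist) {
  x <- as_tibble(dist)
  x$bin <- factor(x$bin, levels = unique(x$bin))
  ggplot(x, aes(x = .data$bin, y = .data$fraction)) +
    geom_col(fill = "grey40") +
    facet_wrap(~family, scales = "free_x") +
    labs(x = NULL, y = "PSM fraction") +
    theme_minimal()
}

#' Heat-map view of the glycan-by-glycosite PSM matrix
#'
#' Shows the densest corner of the matrix: the top glycans (by modified
#' sites) against the top glycosites (by distinct glycans).
#'
#' @param object A `glyco_profile`.
#' @param top_glycans,top_sites How many rows/columns to show.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot glyco_profile
#' @export
autoplot.glyco_profile <- function(object, top_glycans = 20,
                                   top_sites = 30, ...) {
  g <- rank_glycans_by_sites(object, top_glycans)$glycan
  s <- object$sites |>
    dplyr::arrange(dplyr::desc(.data$n_glycans), dplyr::desc(.data$n_psms)) |>
    head(top_sites)
  cells <- object$cells |>
    dplyr::filter(.data$glycan %in% g, .data$site %in% s$site)
  cells$glycan <- factor(cells$glycan, levels = rev(g))
  ggplot(cells, aes(x = .data$site, y = .data$glycan,
                    fill = log10(.data$n_psms + 1))) +
    geom_tile() +
    scale_fill_viridis_c(name = "log10 PSMs + 1") +
    labs(x = "glycosite", y = "glycan") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, size = 6))
}

#' Log2-ratio distributions of a quantified feature set
#'
#' Histogram per design comparison with the fold-cutoff band marked.
#'
#' @param object A `glyco_quant`.
#' @param cutoff Fold cutoff drawn as vertical lines.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot glyco_quant
#' @export
autoplot.glyco_quant <- function(object, cutoff = 2, ...) {
  ggplot(tidy(object), aes(x = .data$log2_ratio)) +
    geom_histogram(bins = 60, fill = "grey30") +
    geom_vline(xintercept = c(-1, 1) * log2(cutoff), linetype = "dashed",
               colour = "red") +
    facet_wrap(~comparison) +
    labs(x = "log2 ratio", y = "features") +
    theme_minimal()
}

#' Tumor/paracancer ratio scatter coloured by differential call
#'
#' @param object A `glyco_calls` table.
#' @param ... Ignored.
#' @return A ggplot of the two tumor-vs-paracancer log2 ratios.
#' @method autoplot glyco_calls
#' @export
autoplot.glyco_calls <- function(object, ...) {
  cutoff <- attr(object, "common_cutoff") %||% 2
  ggplot(as_tibble(object),
         aes(x = .data$log2_tumor_vs_para_lowAFP,
             y = .data$log2_tumor_vs_para_highAFP,
             colour = .data$common_label)) +
    geom_hline(yintercept = c(-1, 1) * log2(cutoff), linetype = "dotted") +
    geom_vline(xintercept = c(-1, 1) * log2(cutoff), linetype = "dotted") +
    geom_point(alpha = 0.6, size = 1) +
    scale_colour_manual(values = c(up = "firebrick", down = "navy",
                                   none = "grey70")) +
    labs(x = "log2 tumor/paracancer (low AFP)",
         y = "log2 tumor/paracancer (high AFP)", colour = "common call") +
    theme_minimal()
}

#' Enrichment bar chart
#'
#' @param object A `glyco_enrichment` table.
#' @param ... Ignored.
#' @return A ggplot of -log10 p per retained term.
#' @method autoplot glyco_enrichment
#' @export
autoplot.glyco_enrichment <- function(object, ...) {
  x <- as_tibble(object)
  x$name <- factor(x$name, levels = rev(x$name))
  ggplot(x, aes(x = -log10(.data$p_value), y = .data$name)) +
    geom_col(fill = "darkorange") +
    labs(x = "-log10 p", y = NULL) +
    theme_minimal()
}
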