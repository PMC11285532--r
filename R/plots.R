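# ggplot2 views of the main result types

#' Volcano plot of a differential-expression table
#'
#' @param de Tibble from [nb_de_test()] / [regional_de()] (one contrast; a
#'   `cell_type` facet is added when several types are present).
#' @param lfc_min,fdr_max Thresholds drawn as guides.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, lfc_min = 0.5, fdr_max = 0.05) {
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$adj_p),
                                   colour = .data$is_deg)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-lfc_min, lfc_min),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(fdr_max),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    (if (dplyr::n_distinct(de$cell_type) > 1) {
      ggplot2::facet_wrap(ggplot2::vars(.data$cell_type))
    } else NULL) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  colour = "DEG") +
    ggplot2::theme_minimal()
}

#' Bubble plot of an enrichment table
#'
#' @param object An `rv_enrichment` tibble from [enrich_table()].
#' @param ... Unused.
#' @return A ggplot object: query x target, point size = overlap, colour =
#'   enrichment score.
#' @export
autoplot.rv_enrichment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$target, y = .data$query,
                                       size = .data$k,
                                       colour = .data$score)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, size = "overlap",
                  colour = "-log10 adj p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Quadrant scatter of regional vs disease fold changes
#'
#' @param shared The `shared` tibble from [concordance()] (one cell type and
#'   disease, or faceted over both).
#' @return A ggplot object.
#' @export
plot_concordance <- function(shared) {
  ggplot2::ggplot(shared, ggplot2::aes(x = .data$log2fc_region,
                                       y = .data$log2fc_disease)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_grid(ggplot2::vars(.data$disease),
                        ggplot2::vars(.data$cell_type)) +
    ggplot2::labs(x = "log2FC (TL/FL)", y = "log2FC (disease/control)") +
    ggplot2::theme_minimal()
}

#' Bar plot of the per-type vulnerability contrast
#'
#' @param vc The `summary` tibble from [vulnerability_contrast()].
#' @return A ggplot object showing GWAS and drug overlap fractions per type.
#' @export
plot_vulnerability <- function(vc) {
  long <- vc |>
    select("cell_type", "frac_gwas", "frac_drug") |>
    tidyr::pivot_longer(-"cell_type", names_to = "family",
                        values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cell_type,
                                     y = .data$fraction,
                                     fill = .data$family)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "fraction of TL-upregulated genes",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
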