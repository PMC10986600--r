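## ggplot2 views of the main result types. These mirror the field's usual
## displays: a genome x sample detection raster, a species x sample
## relative-abundance heatmap with Bray-Curtis leaf ordering, and a
## gene x sample detection map.

#' Detection raster across samples
#'
#' Genomes as rows, samples as columns (grouped by site when available),
#' detected cells filled.
#'
#' @param detection A [detect_genomes()] result.
#' @return A ggplot object.
#' @export
plot_detection <- function(detection) {
  assert_columns(detection, c("genome_id", "sample_id", "detected"),
                 "detection")
  df <- detection
  if ("site" %in% names(df)) df$site <- site_factor(df$site)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id,
                                        y = .data$genome_id,
                                        fill = .data$detected)) +
    ggplot2::geom_tile(colour = NA) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey15",
                                          `TRUE` = "cyan3")) +
    ggplot2::labs(x = "sample", y = "genome", fill = "detected") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if ("site" %in% names(df)) {
    p <- p + ggplot2::facet_grid(~site, scales = "free_x", space = "free_x")
  }
  p
}

#' Relative-abundance heatmap
#'
#' Species x sample heatmap of Q2Q3-based relative abundances with rows
#' and columns in Bray-Curtis leaf order.
#'
#' @param species_abundance An [aggregate_species_abundance()] result.
#' @param order Optional [order_by_bray_curtis()] result; computed when
#'   omitted.
#' @return A ggplot object.
#' @export
plot_abundance <- function(species_abundance, order = NULL) {
  assert_columns(species_abundance, c("species", "sample_id", "abundance"),
                 "species_abundance")
  order <- order %||% order_by_bray_curtis(species_abundance)
  df <- species_abundance |>
    mutate(species = factor(.data$species, levels = order$row_order),
           sample_id = factor(.data$sample_id, levels = order$col_order))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id,
                                        y = .data$species,
                                        fill = .data$abundance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "sample", y = "species", fill = "relative\nabundance") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if ("site" %in% names(df)) {
    p <- p + ggplot2::facet_grid(~site_factor(.data$site),
                                 scales = "free_x", space = "free_x")
  }
  p
}

#' @describeIn gene_detection_map Gene x sample detection raster with
#'   genes in detection-frequency order and samples in within-site
#'   proportion-detected order.
#' @param object A `gene_detection_map`.
#' @param ... Unused.
#' @method autoplot gene_detection_map
#' @export
autoplot.gene_detection_map <- function(object, ...) {
  df <- object$detection |>
    mutate(gene_id = factor(.data$gene_id, levels = object$gene_order),
           sample_id = factor(.data$sample_id, levels = object$sample_order))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$gene_id,
                                   fill = .data$detected)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey15",
                                          `TRUE` = "seagreen3")) +
    ggplot2::labs(x = "sample (top median coverage per site)", y = "gene",
                  fill = "detected") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
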