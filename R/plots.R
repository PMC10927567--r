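# ggplot2 views of the result objects: volcano plots with the S0
# significance boundary, ranked-affinity plots, PCA QC, the binned regional
# t-score heatmap, and the depletion-specificity scatter.

#' Volcano plot of a TREX enrichment result
#'
#' Log2 difference (+RNase H minus -RNase H) against -log10 p, significant
#' proteins coloured, with the hyperbolic significance boundary at the
#' permutation-derived d cut-off overlaid when available.
#'
#' @param object A `trex_enrichment` object from [permutation_fdr()].
#' @param label_top Label the `label_top` most extreme significant proteins
#'   (0 disables labels).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trex_enrichment
#' @export
autoplot.trex_enrichment <- function(object, label_top = 0, ...) {
  res <- tidy(object)
  p <- ggplot2::ggplot(
    res,
    ggplot2::aes(.data$difference, -log10(.data$p),
                 colour = .data$significant)
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
      name = sprintf("FDR <= %.2g", object$alpha)
    ) +
    ggplot2::labs(
      x = sprintf("log2 difference (%s - %s)",
                  object$groups[1], object$groups[2]),
      y = expression(-log[10] ~ italic(p))
    ) +
    ggplot2::theme_minimal()
  if (!is.na(object$d_cut)) {
    grid <- seq(0, max(abs(res$difference)) * 1.05, length.out = 400)
    boundary <- significance_boundary(
      object$s0, object$d_cut, object$df, grid
    )
    p <- p + ggplot2::geom_line(
      data = boundary[!is.na(boundary$neg_log10_p), ],
      ggplot2::aes(.data$difference, .data$neg_log10_p),
      inherit.aes = FALSE, linetype = "dashed", colour = "grey30"
    )
  }
  if (label_top > 0) {
    lab <- res |>
      dplyr::filter(.data$significant) |>
      dplyr::slice_max(abs(.data$d_stat), n = label_top)
    p <- p + ggplot2::geom_text(
      data = lab,
      ggplot2::aes(label = .data$protein_id),
      size = 2.5, vjust = -0.6, show.legend = FALSE
    )
  }
  p
}

#' Ranked relative-affinity plot
#'
#' Proteins ordered by estimated Ka (log10 scale), the view behind ranked
#' interactor plots.
#'
#' @param affinity Tibble from [estimate_affinity()].
#' @param highlight Optional character vector of protein ids to highlight.
#' @return A ggplot object.
#' @export
plot_affinity_rank <- function(affinity, highlight = NULL) {
  df <- affinity |> dplyr::filter(!is.na(.data$ka))
  df$highlight <- if (is.null(highlight)) FALSE else
    df$protein_id %in% highlight
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$ka)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$highlight),
                        show.legend = !is.null(highlight)) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey40", `TRUE` = "firebrick"), name = NULL
    ) +
    ggplot2::labs(x = "Affinity rank", y = expression(K[a])) +
    ggplot2::theme_minimal()
}

#' @describeIn pca_qc PCA QC plot: samples on the first two components,
#'   coloured by group, flagged replicates marked.
#' @param object A `trex_pca` object.
#' @method autoplot trex_pca
#' @export
autoplot.trex_pca <- function(object, ...) {
  co <- object$coordinates
  ggplot2::ggplot(co, ggplot2::aes(.data$pc1, .data$pc2,
                                   colour = .data$group)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$flagged), size = 3) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$variance_fraction[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * (object$variance_fraction[2] %||% 0))
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn assemble_tscore_matrix Binned regional t-score heatmap:
#'   black for scores at or below 0, then red (2-6), orange (6-10) and
#'   yellow (10 or more), rows in clustered display order when available.
#' @param object A `trex_regional` object.
#' @method autoplot trex_regional
#' @export
autoplot.trex_regional <- function(object, ...) {
  long <- tidy(object)
  ord <- object$protein_order %||% object$proteins
  long$protein_id <- factor(long$protein_id, levels = rev(ord))
  long$region <- factor(long$region, levels = object$regions)
  ggplot2::ggplot(long, ggplot2::aes(.data$region, .data$protein_id,
                                     fill = .data$bin)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(
      values = c(`<=0` = "black", `0-2` = "#67000d", `2-6` = "red",
                 `6-10` = "orange", `>=10` = "yellow"),
      name = "t-score"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Depletion-specificity scatter
#'
#' Group-mean log2 TPM in control versus RNase H-treated samples, outliers
#' highlighted; points on the identity line are unaffected by digestion.
#'
#' @param specificity Tibble from [transcriptome_specificity()].
#' @return A ggplot object.
#' @export
plot_specificity_scatter <- function(specificity) {
  ggplot2::ggplot(
    specificity,
    ggplot2::aes(.data$mean_treated, .data$mean_control,
                 colour = .data$outlier)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey50", `TRUE` = "firebrick"), name = "Outlier"
    ) +
    ggplot2::labs(
      x = "mean log2 TPM (+RNase H)", y = "mean log2 TPM (control)"
    ) +
    ggplot2::theme_minimal()
}
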