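#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_vline
#'   geom_tile geom_boxplot scale_fill_gradient2 labs theme_bw
NULL

#' Volcano plot of a moderated DE fit
#'
#' @param object An `nsp_defit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nsp_defit
#' @export
autoplot.nsp_defit <- function(object, ...) {
  r <- object$results[!is.na(object$results$p_adj), , drop = FALSE]
  ggplot(r, aes(x = .data$log2_fc, y = -log10(.data$p_adj),
                colour = .data$call)) +
    geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(up = "firebrick", down = "steelblue", ns = "grey60"),
      name = NULL) +
    geom_vline(xintercept = c(-1, 1) * object$fc_threshold,
               linetype = "dashed", colour = "grey40") +
    geom_hline(yintercept = -log10(object$alpha),
               linetype = "dashed", colour = "grey40") +
    labs(x = "log2 fold change (SILAC ratio)",
         y = "-log10 adjusted p") +
    theme_bw()
}

#' PCA score plot of SILAC ratio profiles
#'
#' @param object An `nsp_pca` from [pca_ratios()].
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2.
#' @method autoplot nsp_pca
#' @export
autoplot.nsp_pca <- function(object, ...) {
  ev <- object$explained_variance
  ggplot(object$scores, aes(x = .data$PC1, y = .data$PC2)) +
    geom_point(size = 2) +
    ggplot2::geom_text(aes(label = .data$run), vjust = -0.8, size = 3) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * ev[2])) +
    theme_bw()
}

#' Heatmap of classified time-course responses
#'
#' @param report Output of [timecourse_report()].
#' @param time_points Ordered time-point labels.
#' @return A ggplot tile map; significant cells are outlined.
#' @export
plot_timecourse_heatmap <- function(report, time_points) {
  fc_cols <- paste0("fc_", time_points)
  sig_cols <- paste0("sig_", time_points)
  long <- report |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    tidyr::pivot_longer(dplyr::all_of(fc_cols), names_to = "time_point",
                        values_to = "log2_fc", names_prefix = "fc_")
  sig <- report |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    tidyr::pivot_longer(dplyr::all_of(sig_cols), names_to = "time_point",
                        values_to = "sig", names_prefix = "sig_")
  long$sig <- sig$sig
  long$time_point <- factor(long$time_point, levels = time_points)
  ggplot(long, aes(x = .data$time_point,
                   y = stats::reorder(.data$gene, -.data$.row),
                   fill = .data$log2_fc)) +
    geom_tile(aes(colour = .data$sig), linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = NA),
                                 guide = "none", na.value = NA) +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick",
                         name = "log2 FC") +
    labs(x = NULL, y = NULL) +
    theme_bw()
}

#' Boxplot of replicate CVs per condition
#'
#' @param cvs Output of [ratio_cv()].
#' @return A ggplot.
#' @export
plot_cv <- function(cvs) {
  ggplot(cvs[!is.na(cvs$cv), ], aes(x = .data$condition, y = .data$cv)) +
    geom_boxplot(outlier.size = 0.5) +
    labs(x = NULL, y = "CV of SILAC ratio (%)") +
    theme_bw()
}
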