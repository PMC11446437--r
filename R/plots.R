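# Plot helpers (ggplot2 is optional; these functions error informatively
# without it). All plots are drawn from the exported point/curve tables, so
# the same data can be replotted elsewhere.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    cs_abort("ggplot2 is required for plotting", "input")
}

#' Bland-Altman plot of per-woman repeatability
#'
#' Per-woman maximum score difference against mean score, with the center line
#' and 95% limits of agreement.
#'
#' @param report a `repeatability_report`.
#' @return a ggplot object.
#' @export
plot_bland_altman <- function(report) {
  need_ggplot()
  stopifnot(inherits(report, "repeatability_report"))
  ggplot2::ggplot(report$points,
                  ggplot2::aes(x = .data$mean_score, y = .data$max_diff)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = report$loa_center,
                        linetype = "dashed", colour = "blue") +
    ggplot2::geom_hline(yintercept = c(report$loa_low, report$loa_high),
                        linetype = "dotted", colour = "blue") +
    ggplot2::coord_cartesian(xlim = c(0, 2)) +
    ggplot2::labs(x = "mean severity score across repeat images",
                  y = "max score difference across repeat images",
                  title = sprintf("95%% LoA width %.3f (%d women)",
                                  report$loa_width, report$n_women_evaluable))
}

#' Retraining saturation curves
#'
#' One-vs-rest AUROC on the held-aside external test set against the number
#' of women added per increment, with bootstrap CI ribbons, per ratio.
#'
#' @param retrain a `retrain_curve`.
#' @return a ggplot object.
#' @export
plot_retrain_curve <- function(retrain) {
  need_ggplot()
  curve <- retrain$curve
  long <- dplyr::bind_rows(
    tibble::tibble(ratio = curve$ratio, n_added = curve$n_added,
                   auc = curve$auroc_normal_ext,
                   lo = curve$auroc_normal_ext_lo, hi = curve$auroc_normal_ext_hi,
                   contrast = "normal vs rest"),
    tibble::tibble(ratio = curve$ratio, n_added = curve$n_added,
                   auc = curve$auroc_precancer_ext,
                   lo = curve$auroc_precancer_ext_lo, hi = curve$auroc_precancer_ext_hi,
                   contrast = "precancer+ vs rest"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_added, y = .data$auc)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(contrast ~ ratio) +
    ggplot2::labs(x = "n (women added per ratio unit)",
                  y = "AUROC on held-aside external test set")
}

#' Heterogeneity projection plot
#'
#' @param projection result of [heterogeneity_projection()].
#' @param colour_by name of the grouping axis to colour by.
#' @return a ggplot object.
#' @export
plot_projection <- function(projection, colour_by) {
  need_ggplot()
  stopifnot(colour_by %in% names(projection$embedding))
  ggplot2::ggplot(projection$embedding,
                  ggplot2::aes(x = .data$dim1, y = .data$dim2,
                               colour = .data[[colour_by]])) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(title = sprintf("separation (%s): %.3f", colour_by,
                                  projection$separation[[colour_by]]))
}
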