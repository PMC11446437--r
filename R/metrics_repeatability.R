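# Test-retest repeatability metrics over repeat images taken at the same
# visit: Bland-Altman statistics on per-woman maximum score differences, 95%
# limits of agreement, and the extreme-disagreement rate.

per_woman_points <- function(predictions) {
  stopifnot(all(c("woman_id", "score") %in% names(predictions)))
  dplyr::summarise(
    dplyr::group_by(predictions, .data$woman_id),
    n_images = dplyr::n(),
    mean_score = mean(.data$score),
    max_diff = max(.data$score) - min(.data$score),
    has_normal = any(.data$pred_class == 0L),
    has_precancer = any(.data$pred_class == 2L),
    .groups = "drop")
}

#' Bland-Altman repeatability report
#'
#' For every woman with at least two repeat images, computes the mean severity
#' score across all her images and the maximum score difference (max - min,
#' i.e. the largest pairwise difference). The 95% limits of agreement are
#' `mean(max_diff) +/- 1.96 * sd(max_diff)` over evaluable women (sample sd,
#' n-1 denominator). Because the literature reports a single "95% LoA" number
#' without defining it, the report exposes the center, both limits, the full
#' width (`loa_high - loa_low`) and the half width (`1.96 * sd`). Women with a
#' single image are excluded and counted separately. The extreme-disagreement
#' percentage (see [extreme_disagreement()]) is included for convenience.
#'
#' @param predictions prediction tibble with `woman_id`, `score` and
#'   `pred_class` columns.
#' @return object of class `repeatability_report`: `points` (tibble woman_id,
#'   mean_score, max_diff over evaluable women), `loa_center`, `loa_low`,
#'   `loa_high`, `loa_width`, `loa_half_width`, `pct_extreme_disagreement`,
#'   `n_women_evaluable`, `n_women_single_image`.
#' @export
bland_altman <- function(predictions) {
  pts <- per_woman_points(predictions)
  ev <- pts[pts$n_images >= 2L, , drop = FALSE]
  if (nrow(ev) < 2L)
    cs_abort("Bland-Altman needs at least 2 women with >=2 repeat images",
             "insufficient_repeats")
  center <- mean(ev$max_diff)
  half <- 1.96 * sd(ev$max_diff)
  structure(list(
    points = ev[, c("woman_id", "n_images", "mean_score", "max_diff")],
    loa_center = center,
    loa_low = center - half,
    loa_high = center + half,
    loa_width = 2 * half,
    loa_half_width = half,
    pct_extreme_disagreement = extreme_disagreement(predictions),
    n_women_evaluable = nrow(ev),
    n_women_single_image = sum(pts$n_images < 2L)),
    class = "repeatability_report")
}

#' Extreme-disagreement percentage
#'
#' Percentage of evaluable women (>= 2 repeat images) for whom some pair of
#' repeat images received predictions two classes apart, i.e. the woman has
#' both a "normal" and a "precancer+" predicted image.
#'
#' @inheritParams bland_altman
#' @return percentage in `[0, 100]`.
#' @export
extreme_disagreement <- function(predictions) {
  stopifnot("pred_class" %in% names(predictions))
  pts <- per_woman_points(predictions)
  ev <- pts[pts$n_images >= 2L, , drop = FALSE]
  if (nrow(ev) == 0L)
    cs_abort("no women with >=2 repeat images", "insufficient_repeats")
  100 * mean(ev$has_normal & ev$has_precancer)
}

#' Repeatability report (alias)
#'
#' Synonym for [bland_altman()]; provided so that the classification and
#' repeatability panels read symmetrically in pipeline code.
#' @inheritParams bland_altman
#' @return a `repeatability_report`.
#' @export
repeatability_report <- function(predictions) bland_altman(predictions)

#' @export
print.repeatability_report <- function(x, ...) {
  cat(sprintf("<repeatability_report> %d evaluable women (%d excluded with one image)\n",
              x$n_women_evaluable, x$n_women_single_image))
  cat(sprintf("  95%% LoA: center %.3f, limits [%.3f, %.3f], width %.3f (half %.3f)\n",
              x$loa_center, x$loa_low, x$loa_high, x$loa_width, x$loa_half_width))
  cat(sprintf("  %% extreme disagreement: %.1f\n", x$pct_extreme_disagreement))
  invisible(x)
}
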