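# Classification-performance metrics: one-vs-rest AUROC with woman-clustered
# bootstrap confidence intervals, confusion matrix, extreme / total
# misclassification rates.

# midrank (Wilcoxon / Mann-Whitney) AUC: probability that a positive-class
# unit outranks a negative one, ties counted 1/2
auc_midrank <- function(score, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest AUROC with woman-clustered bootstrap CI
#'
#' Binarizes the test set as `positive_class` vs rest and computes the
#' probability that a positive image outranks a negative one (midrank tie
#' correction), ranking images by the positive class's own softmax
#' probability. The severity score cannot rank "indeterminate vs rest"
#' monotonically, so the class's own probability is used for every class.
#' Confidence intervals are 2.5/97.5 percentiles over bootstrap resamples
#' drawn *at the woman level* (all of a woman's images move together), since
#' repeat images within a woman are correlated; resamples in which only one
#' class survives are dropped.
#'
#' @param probs matrix/data frame of softmax probabilities (images x 3), or a
#'   numeric vector already containing the ranking score.
#' @param truth integer vector of true classes in 0:2 (or, if `probs` is a
#'   score vector, any labels comparable to `positive_class`).
#' @param positive_class the class treated as positive (0, 1 or 2).
#' @param woman_id optional cluster ids for the bootstrap; images with the
#'   same id are resampled together. Defaults to one cluster per image.
#' @param n_boot number of bootstrap resamples (0 = no CI).
#' @param seed seed for the bootstrap.
#' @return list with `auc`, `ci_low`, `ci_high`, `n_boot_effective`.
#' @export
auroc_ovr <- function(probs, truth, positive_class, woman_id = NULL,
                      n_boot = 0L, seed = 1L) {
  if (is.null(dim(probs))) {
    score <- as.numeric(probs)
  } else {
    probs <- as.matrix(probs)
    stopifnot(positive_class %in% 0:2, ncol(probs) == 3L)
    score <- probs[, positive_class + 1L]
  }
  positive <- truth == positive_class
  if (length(score) != length(positive))
    cs_abort("probs and truth lengths differ", "input")
  if (all(positive) || !any(positive))
    cs_abort("AUROC undefined: only one class present after binarization",
             "undefined_metric")
  auc <- auc_midrank(score, positive)

  ci_low <- ci_high <- NA_real_
  n_eff <- 0L
  if (n_boot >= 1L) {
    if (is.null(woman_id)) woman_id <- as.character(seq_along(score))
    idx_by_woman <- split(seq_along(score), woman_id)
    nw <- length(idx_by_woman)
    boots <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_boot), function(b) {
        take <- sample.int(nw, nw, replace = TRUE)
        idx <- unlist(idx_by_woman[take], use.names = FALSE)
        auc_midrank(score[idx], positive[idx])
      }, numeric(1))
    })
    boots <- boots[!is.na(boots)]
    n_eff <- length(boots)
    if (n_eff >= 2L) {
      qs <- quantile(boots, c(0.025, 0.975), names = FALSE, type = 7)
      ci_low <- qs[1L]
      ci_high <- qs[2L]
    }
  }
  list(auc = auc, ci_low = ci_low, ci_high = ci_high, n_boot_effective = n_eff)
}

#' 3x3 confusion matrix
#'
#' @param truth integer vector of true classes in 0:2 (rows).
#' @param pred integer vector of predicted classes in 0:2 (columns).
#' @return 3x3 integer matrix of counts, rows = truth, columns = prediction.
#' @export
confusion_matrix3 <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  if (!all(truth %in% 0:2) || !all(pred %in% 0:2))
    cs_abort("classes must be in 0:2", "input")
  m <- table(factor(truth, levels = 0:2), factor(pred, levels = 0:2))
  m <- matrix(as.integer(m), 3L, 3L,
              dimnames = list(truth = names(class_labels()),
                              predicted = names(class_labels())))
  m
}

#' Extreme and total misclassification rates
#'
#' Extreme misclassifications are the two-class errors: a normal image
#' predicted precancer+ or vice versa, i.e. cells (0,2) and (2,0) of the
#' confusion matrix. Rates are percentages of all test images.
#'
#' @param confusion 3x3 nonnegative count matrix (rows truth, cols prediction).
#' @return list with `pct_extreme` and `pct_total`.
#' @export
misclassification_rates <- function(confusion) {
  m <- as.matrix(confusion)
  stopifnot(all(dim(m) == c(3L, 3L)))
  if (any(m < 0) || any(m != round(m)))
    cs_abort("confusion must contain nonnegative integer counts", "input")
  total <- sum(m)
  if (total == 0) cs_abort("misclassification rates undefined for an empty matrix",
                           "undefined_metric")
  list(pct_extreme = 100 * (m[1L, 3L] + m[3L, 1L]) / total,
       pct_total = 100 * (total - sum(diag(m))) / total)
}

#' Classification metrics report for one model / test-set pair
#'
#' Computes the full classification panel at the image level: normal-vs-rest
#' and precancer+-vs-rest AUROCs with woman-clustered bootstrap CIs, the 3x3
#' confusion matrix and the extreme / total misclassification percentages.
#'
#' @param predictions prediction tibble (as from [predict_standin()]): needs
#'   `woman_id`, `p0`, `p1`, `p2`, `pred_class`.
#' @param truth either an integer vector (one true class per prediction row)
#'   or a `women` tibble with `woman_id` and `true_class` to join on.
#' @param n_boot bootstrap resamples for the AUROC CIs.
#' @param seed bootstrap seed.
#' @return object of class `metrics_report`.
#' @export
evaluate_predictions <- function(predictions, truth, n_boot = 1000L, seed = 1L) {
  stopifnot(all(c("woman_id", "p0", "p1", "p2", "pred_class") %in% names(predictions)))
  if (is.data.frame(truth)) {
    stopifnot(all(c("woman_id", "true_class") %in% names(truth)))
    y <- truth$true_class[match(predictions$woman_id, truth$woman_id)]
    if (anyNA(y)) cs_abort("some predictions have no matching woman in truth", "input")
  } else {
    y <- as.integer(truth)
    if (length(y) != nrow(predictions))
      cs_abort("truth length must match predictions", "input")
  }
  probs <- as.matrix(predictions[, c("p0", "p1", "p2")])
  conf <- confusion_matrix3(y, predictions$pred_class)
  rates <- misclassification_rates(conf)
  structure(list(
    auroc_normal = auroc_ovr(probs, y, 0L, predictions$woman_id, n_boot,
                             seed = sub_seed(seed, 11L)),
    auroc_precancer = auroc_ovr(probs, y, 2L, predictions$woman_id, n_boot,
                                seed = sub_seed(seed, 12L)),
    confusion = conf,
    pct_extreme_mis = rates$pct_extreme,
    pct_total_mis = rates$pct_total,
    n_images = nrow(predictions),
    n_women = length(unique(predictions$woman_id))),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt_ci <- function(a) sprintf("%.3f [%.3f, %.3f]", a$auc, a$ci_low, a$ci_high)
  cat(sprintf("<metrics_report> %d images / %d women\n", x$n_images, x$n_women))
  cat("  AUROC normal vs rest:    ", fmt_ci(x$auroc_normal), "\n")
  cat("  AUROC precancer+ vs rest:", fmt_ci(x$auroc_precancer), "\n")
  cat(sprintf("  %% extreme mis.: %.1f   %% total mis.: %.1f\n",
              x$pct_extreme_mis, x$pct_total_mis))
  print(x$confusion)
  invisible(x)
}
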