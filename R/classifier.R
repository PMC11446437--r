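# Stand-in classifier: multinomial logistic regression (linear softmax) over
# feature vectors, trained full-batch by gradient descent with a small ridge
# penalty, plus the continuous severity score.
#
# This deliberately minimal model is the smallest classifier that exhibits the
# phenomena under study (device-shift degradation, retraining recovery,
# saturation); the production CNN it stands in for is out of scope here.

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Continuous severity score of a softmax output
#'
#' The class-index-weighted average of the softmax probabilities,
#' `score = sum_i i * p_i` with classes labeled `0, ..., k-1`: the expected
#' value of the predicted ordinal class. For a three-class model the score
#' lies in `[0, 2]`.
#'
#' @param probs numeric vector on the probability simplex, or a matrix with
#'   one simplex row per image.
#' @return numeric score (one per row).
#' @export
severity_score <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  probs <- as.matrix(probs)
  if (any(probs < -1e-9) || any(abs(rowSums(probs) - 1) > 1e-6))
    cs_abort("probs rows must lie on the probability simplex", "input")
  as.numeric(probs %*% (seq_len(ncol(probs)) - 1L))
}

# woman-level class-balanced subsample: returns the woman ids to keep so that
# per-class woman counts are in ratio N:I:P (largest multiple that fits)
balance_women <- function(women_class, balance_ratio) {
  r <- as.integer(balance_ratio)
  check_config(length(r) == 3L && all(r >= 0L) && sum(r) > 0L,
               "balance_ratio must be 3 nonnegative integers")
  by_class <- split(names(women_class), factor(women_class, levels = 0:2))
  avail <- vapply(by_class, length, integer(1))
  m <- suppressWarnings(min((avail %/% r)[r > 0L]))
  if (!is.finite(m) || m < 1L)
    cs_abort(sprintf(
      "cannot balance at ratio %s: available women per class are %s",
      paste(r, collapse = ":"), paste(avail, collapse = "/")), "sampling")
  keep <- character(0)
  for (k in 1:3) {
    if (r[k] == 0L) next
    keep <- c(keep, sort(by_class[[k]])[sample.int(avail[k], r[k] * m)])
  }
  keep
}

#' Train the stand-in classifier
#'
#' Fits a 3-class multinomial logistic regression by full-batch gradient
#' descent on the ridge-penalized cross-entropy, after standardizing features
#' with training-set statistics (frozen into the model). If `balance_ratio`
#' is given, the training set is first subsampled *at the woman level* without
#' replacement so that per-class woman counts are in the requested
#' normal:indeterminate:precancer+ ratio (the largest multiple that fits);
#' all images of a selected woman are kept. Weights are initialized at zero,
#' so given the (sub)sampled data the fit is deterministic; the seed governs
#' only the balancing draw.
#'
#' @param features numeric matrix (images x d) or an images tibble with
#'   `f1..fd` columns.
#' @param labels integer vector of true classes in 0:2, one per image.
#' @param woman_id character vector, one per image; required when
#'   `balance_ratio` is used.
#' @param balance_ratio integer triple N:I:P, or NULL for no balancing.
#' @param seed integer seed for the balancing draw.
#' @param learning_rate gradient-descent step size (standardized features).
#' @param max_iter maximum number of full-batch iterations.
#' @param tol stop when the penalized loss improves by less than this.
#' @param l2 ridge penalty on the non-intercept weights.
#' @return object of class `standin_model`: weights (3 x (d+1), intercept
#'   first), standardization constants, and training metadata.
#' @export
train_standin <- function(features, labels, woman_id = NULL,
                          balance_ratio = NULL, seed = 1L,
                          learning_rate = 1.0, max_iter = 4000L,
                          tol = 1e-9, l2 = 1e-4) {
  X <- if (is.data.frame(features)) feature_matrix(features) else as.matrix(features)
  y <- as.integer(labels)
  if (length(y) != nrow(X)) cs_abort("labels length must match rows of features", "input")
  if (!all(y %in% 0:2)) cs_abort("labels must be in 0:2", "input")

  if (!is.null(balance_ratio)) {
    if (is.null(woman_id)) cs_abort("balance_ratio requires woman_id", "input")
    wc <- tapply(y, woman_id, function(v) v[1L])
    mixed <- tapply(y, woman_id, function(v) length(unique(v)) > 1L)
    if (any(mixed)) cs_abort("a woman has images with differing labels", "input")
    keep <- withr::with_seed(as.integer(seed), balance_women(wc, balance_ratio))
    sel <- woman_id %in% keep
    X <- X[sel, , drop = FALSE]
    y <- y[sel]
    woman_id <- woman_id[sel]
  }
  if (length(unique(y)) < 2L)
    cs_abort("training set contains a single class", "degenerate_training")

  center <- colMeans(X)
  scale_ <- apply(X, 2L, sd)
  scale_[!is.finite(scale_) | scale_ < 1e-12] <- 1
  Xs <- cbind(1, sweep(sweep(X, 2L, center), 2L, scale_, `/`))

  n <- nrow(Xs)
  d1 <- ncol(Xs)
  Y <- matrix(0, n, 3L)
  Y[cbind(seq_len(n), y + 1L)] <- 1
  W <- matrix(0, 3L, d1)
  pen_mask <- matrix(c(0, rep(1, d1 - 1L)), 3L, d1, byrow = TRUE)

  loss_prev <- Inf
  iters <- 0L
  for (it in seq_len(max_iter)) {
    P <- softmax_rows(Xs %*% t(W))
    loss <- -mean(log(pmax(P[cbind(seq_len(n), y + 1L)], 1e-300))) +
      l2 / 2 * sum((W * pen_mask)^2)
    grad <- crossprod(P - Y, Xs) / n + l2 * (W * pen_mask)
    W <- W - learning_rate * grad
    iters <- it
    if (abs(loss_prev - loss) < tol) break
    loss_prev <- loss
  }
  dimnames(W) <- list(names(class_labels()),
                      c("(intercept)", feature_names(d1 - 1L)))
  structure(list(
    weights = W, center = center, scale = scale_,
    meta = list(seed = as.integer(seed), learning_rate = learning_rate,
                max_iter = max_iter, tol = tol, l2 = l2,
                balance_ratio = balance_ratio,
                n_images = n,
                n_women = if (is.null(woman_id)) NA_integer_ else
                  length(unique(woman_id)),
                iterations = iters, final_loss = loss_prev)),
    class = "standin_model")
}

#' @export
print.standin_model <- function(x, ...) {
  cat(sprintf("<standin_model> %d features, trained on %d images (%s women), %d iterations\n",
              ncol(x$weights) - 1L, x$meta$n_images,
              ifelse(is.na(x$meta$n_women), "?", x$meta$n_women),
              x$meta$iterations))
  invisible(x)
}

#' Predict with the stand-in classifier
#'
#' Applies the frozen training-set standardization, computes softmax
#' probabilities, the continuous severity score and the argmax class (ties
#' broken toward the lower, less severe class).
#'
#' @param model a `standin_model`.
#' @param newdata numeric matrix (images x d) or an images tibble with
#'   `image_id`, `woman_id` and `f1..fd` columns.
#' @param image_id,woman_id optional id vectors when `newdata` is a matrix.
#' @return tibble of prediction rows: image_id, woman_id, p0, p1, p2, score,
#'   pred_class.
#' @export
predict_standin <- function(model, newdata, image_id = NULL, woman_id = NULL) {
  stopifnot(inherits(model, "standin_model"))
  if (is.data.frame(newdata)) {
    if (is.null(image_id) && "image_id" %in% names(newdata)) image_id <- newdata$image_id
    if (is.null(woman_id) && "woman_id" %in% names(newdata)) woman_id <- newdata$woman_id
    X <- feature_matrix(newdata)
  } else {
    X <- as.matrix(newdata)
  }
  d <- ncol(model$weights) - 1L
  if (ncol(X) != d)
    cs_abort(sprintf("feature dimension %d does not match model dimension %d",
                     ncol(X), d), "input")
  n <- nrow(X)
  if (is.null(image_id)) image_id <- sprintf("img_%05d", seq_len(n))
  if (is.null(woman_id)) woman_id <- image_id

  Xs <- cbind(1, sweep(sweep(X, 2L, model$center), 2L, model$scale, `/`))
  P <- softmax_rows(Xs %*% t(model$weights))
  tibble::tibble(
    image_id = as.character(image_id),
    woman_id = as.character(woman_id),
    p0 = P[, 1L], p1 = P[, 2L], p2 = P[, 3L],
    score = severity_score(P),
    pred_class = max.col(P, ties.method = "first") - 1L)
}

#' Predict every image of a cohort
#'
#' Convenience wrapper: runs [predict_standin()] on the cohort's images and
#' attaches each woman's site, device and true class.
#'
#' @param model a `standin_model`.
#' @param cohort a `cervshift_cohort`.
#' @return prediction tibble with site, device and true_class columns added.
#' @export
predict_cohort <- function(model, cohort) {
  stopifnot(inherits(cohort, "cervshift_cohort"))
  preds <- predict_standin(model, cohort$images)
  dplyr::left_join(preds,
                   dplyr::select(cohort$women, "woman_id", "site", "device",
                                 "true_class"),
                   by = "woman_id")
}
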