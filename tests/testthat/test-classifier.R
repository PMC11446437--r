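# Stand-in classifier: severity score, softmax invariants, training
# determinism, woman-level class balancing, and an independent multinomial
# cross-check.

test_that("severity score equals the class-index-weighted probability sum", {
  expect_identical(severity_score(c(0, 0, 1)), 2)
  expect_identical(severity_score(c(1, 0, 0)), 0)
  expect_equal(severity_score(rep(1 / 3, 3)), 1)

  withr::with_seed(404L, {
    P <- rand_simplex(10000L)
    oracle <- P[, 2L] * 1 + P[, 3L] * 2  # direct sum_i i * p_i
    expect_equal(severity_score(P), oracle, tolerance = 1e-12)
  })
  expect_error(severity_score(c(0.5, 0.2, 0.1)), class = "cervshift_error_input")
})

test_that("moving probability mass to a higher class never decreases the score", {
  withr::with_seed(405L, {
    P <- rand_simplex(500L)
    for (pair in list(c(1L, 2L), c(1L, 3L), c(2L, 3L))) {
      i <- pair[1L]; j <- pair[2L]
      delta <- P[, i] * 0.5
      Q <- P
      Q[, i] <- Q[, i] - delta
      Q[, j] <- Q[, j] + delta
      expect_true(all(severity_score(Q) >= severity_score(P) - 1e-12))
    }
  })
})

test_that("predictions live on the probability simplex and score the oracle", {
  withr::with_seed(406L, {
    W <- matrix(rnorm(3 * 6), 3L, 6L)
    model <- mk_model(W)
    X <- matrix(rnorm(10000L * 5L, sd = 3), ncol = 5L)
    preds <- predict_standin(model, X)
    probs <- as.matrix(preds[, c("p0", "p1", "p2")])
    expect_true(all(probs >= 0))
    expect_true(all(abs(rowSums(probs) - 1) < 1e-9))
    expect_equal(preds$score, as.numeric(probs %*% 0:2), tolerance = 1e-12)
    expect_true(all(preds$score >= 0 & preds$score <= 2))
    # argmax with lowest-class tie-break
    expect_identical(preds$pred_class,
                     as.integer(apply(probs, 1L, which.max)) - 1L)
  })
  # zero weights: uniform probabilities, score exactly 1
  z <- predict_standin(mk_model(matrix(0, 3L, 3L)), matrix(rnorm(10L), 5L, 2L))
  expect_equal(z$p0, rep(1 / 3, 5L))
  expect_equal(z$score, rep(1, 5L))
  expect_identical(z$pred_class, rep(0L, 5L))  # tie broken toward normal
  expect_error(predict_standin(mk_model(matrix(0, 3L, 3L)), matrix(0, 2L, 5L)),
               class = "cervshift_error_input")
})

make_blobs <- function(n_per_class, centers, sd = 0.5, seed = 1L) {
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
      sweep(matrix(rnorm(n_per_class * ncol(centers), sd = sd),
                   n_per_class), 2L, centers[k, ], `+`)))
    list(X = X, y = rep(seq_len(nrow(centers)) - 1L, each = n_per_class))
  })
}

test_that("training separates separable classes and is deterministic", {
  blobs <- make_blobs(30L, rbind(c(0, 0), c(10, 0), c(0, 10)), sd = 0.5, seed = 2L)
  m1 <- train_standin(blobs$X, blobs$y, seed = 3L)
  preds <- predict_standin(m1, blobs$X)
  expect_equal(mean(preds$pred_class == blobs$y), 1.0)

  m2 <- train_standin(blobs$X, blobs$y, seed = 3L)
  expect_identical(m1$weights, m2$weights)

  expect_error(train_standin(blobs$X[1:30, ], blobs$y[1:30]),
               class = "cervshift_error_degenerate_training")
})

test_that("class balancing subsamples women to the requested ratio", {
  wc <- setNames(c(rep(0L, 25L), rep(1L, 21L), rep(2L, 9L)),
                 sprintf("w%03d", 1:55))
  keep <- withr::with_seed(8L, cervshift:::balance_women(wc, c(2L, 2L, 1L)))
  # largest multiple: m = min(12, 10, 9) = 9 -> 18/18/9 women
  expect_equal(as.integer(table(factor(wc[keep], levels = 0:2))),
               c(18L, 18L, 9L))
  expect_false(anyDuplicated(keep) > 0)
  expect_error(cervshift:::balance_women(wc[wc != 2L], c(2L, 2L, 1L)),
               class = "cervshift_error_sampling")

  # end to end: 2 images per woman, balanced training keeps whole women
  X <- matrix(rnorm(110L * 2L), 110L)
  y <- rep(wc, each = 2L)
  wid <- rep(names(wc), each = 2L)
  m <- train_standin(X, y, woman_id = wid,
                     balance_ratio = c(2L, 2L, 1L), seed = 8L)
  expect_equal(m$meta$n_women, 45L)
  expect_equal(m$meta$n_images, 90L)
})

test_that("fit agrees with an independent multinomial-logistic implementation", {
  skip_if_not_installed("nnet")
  blobs <- make_blobs(200L, rbind(c(0, 0, 0), c(2, 0.5, 0), c(4, 1, 0.5)),
                      sd = 1.2, seed = 9L)
  ours <- train_standin(blobs$X, blobs$y, seed = 1L)
  preds <- predict_standin(ours, blobs$X)

  df <- data.frame(y = factor(blobs$y), blobs$X)
  ref <- nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 500L)
  ref_class <- as.integer(as.character(predict(ref, df)))
  agree <- mean(preds$pred_class == ref_class)
  expect_gt(agree, 0.95)

  ref_probs <- predict(ref, df, type = "probs")
  a_ours <- auroc_ovr(as.matrix(preds[, c("p0", "p1", "p2")]), blobs$y, 2L)
  a_ref <- auroc_ovr(ref_probs, blobs$y, 2L)
  expect_equal(a_ours$auc, a_ref$auc, tolerance = 0.01)
})

test_that("a model trained on one device loses AUROC on a shifted device", {
  seed_cfg <- default_seed_cohort_config(n_women_per_class = c(100L, 100L, 100L),
                                         seed = 61L)
  ext_cfg <- small_ext_cohort_config(seed = 62L)
  seed_co <- generate_cohort(seed_cfg)
  ext_co <- generate_cohort(ext_cfg)
  model <- train_standin(seed_co$images, cervshift:::cohort_image_labels(seed_co),
                         woman_id = seed_co$images$woman_id,
                         balance_ratio = c(2L, 2L, 1L), seed = 63L)
  in_dev <- evaluate_predictions(predict_cohort(model, seed_co), seed_co$women,
                                 n_boot = 0L)
  out_dev <- evaluate_predictions(predict_cohort(model, ext_co), ext_co$women,
                                  n_boot = 0L)
  expect_gt(in_dev$auroc_normal$auc, out_dev$auroc_normal$auc)
  expect_gt(in_dev$auroc_precancer$auc, out_dev$auroc_precancer$auc)
})
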