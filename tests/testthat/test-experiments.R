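# Experiment orchestration: held-out selection, nesting, ratio accounting,
# the out-of-the-box anchor, the model panel and the projection statistic.

rc_small <- run_incremental_retraining(small_experiment_config())

test_that("held-out selection reserves women for the largest increment", {
  ext <- generate_cohort(default_ext_cohort_config())
  ids <- select_heldout(ext, 230L, c(0L, 70L),
                        list(c(1L, 1L, 1L), c(2L, 2L, 1L)), seed = 4L)
  expect_equal(length(ids), 230L)
  cls <- ext$women$true_class[match(ids, ext$women$woman_id)]
  # the reserve binds: 204-140 / 157-140 / 219-70 leaves exactly 64/17/149
  expect_equal(as.integer(table(factor(cls, levels = 0:2))), c(64L, 17L, 149L))
  # pool still covers the largest increment at both ratios
  pool_cls <- ext$women$true_class[!ext$women$woman_id %in% ids]
  expect_true(all(table(factor(pool_cls, levels = 0:2)) >= c(140L, 140L, 70L)))

  expect_error(select_heldout(ext, 300L, c(0L, 70L), list(c(2L, 2L, 1L)), 4L),
               class = "cervshift_error_sampling")
  err <- tryCatch(select_heldout(ext, 10L, c(0L, 150L), list(c(2L, 2L, 1L)), 4L),
                  error = identity)
  expect_s3_class(err, "cervshift_error_sampling")
  expect_match(conditionMessage(err), "normal")  # names the deficient class
})

test_that("increments are nested with exact ratio accounting and a fixed held-out set", {
  cfg <- rc_small$config
  ext <- cervshift:::experiment_cohorts(cfg)$ext
  curve <- rc_small$curve
  expect_equal(nrow(curve), length(cfg$increments) * length(cfg$ratios))

  for (rlab in unique(curve$ratio)) {
    r <- as.integer(strsplit(rlab, ":")[[1L]])
    rows <- curve[curve$ratio == rlab, ]
    prev <- character(0)
    for (i in seq_len(nrow(rows))) {
      ids <- rows$added_ids[[i]]
      n <- rows$n_added[i]
      expect_true(all(prev %in% ids))  # nesting
      cls <- ext$women$true_class[match(ids, ext$women$woman_id)]
      expect_equal(as.integer(table(factor(cls, levels = 0:2))), r * n)
      expect_equal(rows$women_added_total[i], sum(r) * n)
      expect_true(length(intersect(ids, rc_small$heldout_ids)) == 0L)
      prev <- ids
    }
  }
})

test_that("the n = 0 row equals out-of-the-box inference on the held-out sets", {
  cfg <- rc_small$config
  co <- cervshift:::experiment_cohorts(cfg)
  ext_heldout <- subset_cohort(co$ext, rc_small$heldout_ids)
  seed_test <- subset_cohort(co$seed, rc_small$seed_test_ids)
  oob_ext <- evaluate_predictions(predict_cohort(rc_small$base_model, ext_heldout),
                                  ext_heldout$women, n_boot = 0L)
  oob_seed <- evaluate_predictions(predict_cohort(rc_small$base_model, seed_test),
                                   seed_test$women, n_boot = 0L)
  for (rlab in unique(rc_small$curve$ratio)) {
    row0 <- rc_small$curve[rc_small$curve$ratio == rlab &
                             rc_small$curve$n_added == 0L, ]
    expect_equal(row0$auroc_normal_ext, oob_ext$auroc_normal$auc)
    expect_equal(row0$auroc_precancer_ext, oob_ext$auroc_precancer$auc)
    expect_equal(row0$pct_total_mis_ext, oob_ext$pct_total_mis)
    expect_equal(row0$auroc_precancer_seed, oob_seed$auroc_precancer$auc)
  }
})

test_that("heterogeneity suite validates its configuration", {
  cfg <- small_experiment_config()
  cfg$heldout_geography <- "Atlantis"
  expect_error(run_heterogeneity_suite(cfg), class = "cervshift_error_config")
  expect_error(experiment_config(increments = c(5L, 10L)),
               class = "cervshift_error_config")
  expect_error(experiment_config(increments = c(0L, 10L, 10L)),
               class = "cervshift_error_config")
})

test_that("with no device or geography shift the three runs are statistically alike", {
  seed_cfg <- cohort_config(
    sites = list(site_spec("sa", "dev_x", c(40L, 40L, 40L)),
                 site_spec("sb", "dev_y", c(40L, 40L, 40L))),
    seed = 1L)
  ext_cfg <- cohort_config(
    sites = list(site_spec("Bolivia", "dev_z", c(15L, 15L, 15L)),
                 site_spec("Kenya", "dev_z", c(15L, 15L, 15L))),
    seed = 2L)
  het <- run_heterogeneity_suite(experiment_config(
    seed_cohort_config = seed_cfg, ext_cohort_config = ext_cfg,
    n_boot = 100L, master_seed = 12L))
  m <- lapply(het$runs, `[[`, "metrics")
  expect_true(ci_overlap(m$seed_test$auroc_normal, m$ext_oob$auroc_normal))
  expect_true(ci_overlap(m$seed_test$auroc_precancer, m$ext_oob$auroc_precancer))
  expect_true(ci_overlap(m$seed_test$auroc_normal, m$heldout_geo$auroc_normal))
  expect_true(ci_overlap(m$seed_test$auroc_precancer, m$heldout_geo$auroc_precancer))
})

test_that("model panel orders by mean score and selects a stratified subset", {
  withr::with_seed(55L, {
    n <- 90L
    images <- tibble::as_tibble(cbind(
      tibble::tibble(image_id = sprintf("im%03d", 1:n),
                     woman_id = sprintf("im%03d", 1:n)),
      tibble::as_tibble(matrix(rnorm(n * 2L), n,
                               dimnames = list(NULL, c("f1", "f2"))))))
    truth <- rep(0:2, each = 30L)
    m1 <- mk_model(rbind(c(0, -2, 0), c(0, 0, 0), c(0, 2, 0)))
    m2 <- mk_model(rbind(c(0.5, -1, 0.2), c(0, 0, 0), c(-0.5, 1, -0.2)))

    # a single model: panel order is that model's own score order
    pan1 <- model_panel(list(only = m1), images, truth, per_class = 30L)
    s1 <- predict_standin(m1, images)
    for (k in 0:2) {
      in_class <- pan1$panel[pan1$panel$true_class == k, ]
      expect_equal(in_class$mean_score,
                   sort(s1$score[truth == k]), tolerance = 1e-12)
      expect_equal(in_class$panel_rank, seq_len(30L))
    }

    # mean score across models equals the direct average
    pan <- model_panel(list(a = m1, b = m2), images, truth, per_class = 10L,
                       seed = 9L)
    s2 <- predict_standin(m2, images)
    direct <- (s1$score + s2$score) / 2
    names(direct) <- images$image_id
    expect_equal(pan$panel$mean_score, unname(direct[pan$panel$image_id]),
                 tolerance = 1e-12)
    expect_equal(as.integer(table(pan$panel$true_class)), rep(10L, 3L))
    expect_true(all(diff(pan$panel$panel_rank[pan$panel$true_class == 1L]) == 1L))
    # per-model predictions exported for exactly the selected images
    expect_setequal(unique(pan$predictions$image_id), pan$panel$image_id)

    expect_error(model_panel(list(m1), images, truth, per_class = 31L),
                 class = "cervshift_error_sampling")
  })
})

test_that("projection separation is high for split clusters and near zero for one cloud", {
  withr::with_seed(66L, {
    a <- matrix(rnorm(200L * 4L), 200L)
    b <- sweep(matrix(rnorm(200L * 4L), 200L), 2L, c(10, 0, 0, 0), `+`)
    proj <- heterogeneity_projection(rbind(a, b),
                                     list(group = rep(c("a", "b"), each = 200L)))
    expect_gt(proj$separation[["group"]], 0.8)

    null_proj <- heterogeneity_projection(
      rbind(a, a + rnorm(length(a), sd = 1e-6)),
      list(group = rep(c("a", "b"), each = 200L)))
    expect_lt(abs(null_proj$separation[["group"]]), 0.15)

    expect_error(heterogeneity_projection(a, list(group = rep("a", 200L))),
                 class = "cervshift_error_undefined_metric")
  })
})
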