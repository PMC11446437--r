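# Synthetic cohort generator: determinism, enrolment bookkeeping, feature
# geometry and the diagnostic-fact round trip.

test_that("cohort generation is deterministic and honors per-site class counts", {
  cfg <- tiny_cohort_config()
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$women, c2$women)
  expect_identical(c1$images, c2$images)

  expect_equal(nrow(c1$women), 18L)
  tab <- table(c1$women$site, c1$women$true_class)
  expect_true(all(tab == 3L))
  expect_true(all(c1$women$n_images >= 1L))
  expect_equal(sort(unique(c1$images$woman_id)), sort(c1$women$woman_id))
  img_per_woman <- table(c1$images$woman_id)
  expect_equal(as.integer(img_per_woman[c1$women$woman_id]), c1$women$n_images)

  empty <- generate_cohort(tiny_cohort_config(n = c(0L, 0L, 0L)))
  expect_equal(nrow(empty$women), 0L)
  expect_equal(nrow(empty$images), 0L)
})

test_that("invalid configurations are rejected", {
  expect_error(tiny_cohort_config(images_per_woman = c(0.5, 0.5, 0.5, 0.5)),
               class = "cervshift_error_config")
  expect_error(tiny_cohort_config(within_woman_sd = -1),
               class = "cervshift_error_config")
  expect_error(tiny_cohort_config(n_features = 1L),
               class = "cervshift_error_config")
  expect_error(site_spec("a", "d", c(1L, -1L, 0L)),
               class = "cervshift_error_config")
})

test_that("default external cohort reproduces the study's enrolment structure", {
  cfg <- default_ext_cohort_config()
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$women), 580L)
  expect_equal(as.integer(table(factor(co$women$true_class, levels = 0:2))),
               c(204L, 157L, 219L))
  expect_equal(length(unique(co$women$site)), 6L)
  expect_equal(unique(co$women$device), "smartphone_j8")
  # geography offsets are small relative to the device translation
  for (s in cfg$sites) {
    expect_lt(sqrt(sum(s$geo_shift^2)), sqrt(sum(s$device_shift^2)))
  }
})

test_that("device translation is recovered by per-class sample means", {
  cfg <- cohort_config(
    sites = list(
      site_spec("ref", "dev_ref", c(300L, 0L, 0L)),
      site_spec("new", "dev_new", c(300L, 0L, 0L), device_shift = c(0, 4))),
    n_features = 4L, seed = 21L)
  co <- generate_cohort(cfg)
  X <- cervshift:::feature_matrix(co$images)
  site <- co$women$site[match(co$images$woman_id, co$women$woman_id)]
  diff <- colMeans(X[site == "new", ]) - colMeans(X[site == "ref", ])
  expect_equal(unname(diff), c(0, 4, 0, 0), tolerance = 0.1)
})

test_that("device-level shift dominates geography-level shift in feature space", {
  seed_co <- generate_cohort(default_seed_cohort_config(
    n_women_per_class = c(80L, 80L, 80L)))
  ext_co <- generate_cohort(default_ext_cohort_config())
  lbl <- function(co, col) co$women[[col]][match(co$images$woman_id, co$women$woman_id)]
  X <- rbind(cervshift:::feature_matrix(seed_co$images),
             cervshift:::feature_matrix(ext_co$images))
  device <- c(lbl(seed_co, "device"), lbl(ext_co, "device"))
  cls <- c(lbl(seed_co, "true_class"), lbl(ext_co, "true_class"))
  ext_site <- lbl(ext_co, "site")
  ext_cls <- lbl(ext_co, "true_class")
  Xe <- cervshift:::feature_matrix(ext_co$images)

  centroid_dist <- function(M, g) {
    cm <- apply(M, 2L, function(v) tapply(v, g, mean))
    mean(dist(cm))
  }
  # same class, different devices (incl. the new one) vs same device (the new
  # smartphone), different geographies
  dev_dist <- mean(vapply(0:2, function(k)
    centroid_dist(X[cls == k, ], device[cls == k]), numeric(1)))
  # restrict to sites contributing that class to avoid empty cells
  geo_dist <- mean(vapply(0:2, function(k) {
    keep <- ext_cls == k
    sites_k <- names(which(table(ext_site[keep]) >= 10L))
    keep <- keep & ext_site %in% sites_k
    centroid_dist(Xe[keep, ], ext_site[keep])
  }, numeric(1)))
  expect_gt(dev_dist, geo_dist)

  proj <- heterogeneity_projection(
    X, list(device = device), max_n = 1500L, seed = 3L)
  proj_geo <- heterogeneity_projection(
    Xe, list(geography = ext_site), max_n = 1500L, seed = 3L)
  expect_gt(proj$separation[["device"]], proj_geo$separation[["geography"]])
})

test_that("diagnostic facts round-trip to the true class under the rule engine", {
  for (cls in 0:2) {
    for (site in c("Bolivia", "Brazil")) {
      facts <- lapply(1:1000, function(s)
        generate_diagnostic_facts(cls, site, seed = s))
      recovered <- assign_ground_truth(
        vapply(facts, `[[`, character(1), "histology"),
        vapply(facts, `[[`, character(1), "hrhpv"),
        vapply(facts, `[[`, character(1), "expert_label"),
        site)
      expect_true(all(recovered == cls))
      if (cls == 2L && site == "Brazil") {
        expect_true(all(vapply(facts, `[[`, character(1), "histology") %in%
                          c("CIN3", "AIS", "cancer")))
      }
      if (cls == 0L) {
        expect_true(all(vapply(facts, `[[`, character(1), "histology") %in%
                          c("lt_CIN2", "missing")))
        expect_true(all(vapply(facts, `[[`, character(1), "expert_label") == "normal"))
      }
    }
  }
  # same seed, same draw
  expect_identical(generate_diagnostic_facts(1L, "Kenya", seed = 99L),
                   generate_diagnostic_facts(1L, "Kenya", seed = 99L))
})

test_that("repeat-image correlation matches the analytic variance ratio", {
  w_sd <- 0.7
  i_sd <- 0.25
  cfg <- cohort_config(
    sites = list(site_spec("one", "dev", c(500L, 0L, 0L))),
    within_woman_sd = w_sd, between_image_sd = i_sd,
    n_features = 2L, seed = 31L)
  co <- generate_cohort(cfg)
  f1 <- co$images$f1
  wid <- factor(co$images$woman_id)
  k_i <- as.integer(table(wid))
  N <- length(f1)
  a <- nlevels(wid)
  k0 <- (N - sum(k_i^2) / N) / (a - 1)
  ms <- summary(stats::aov(f1 ~ wid))[[1L]][["Mean Sq"]]
  icc <- (ms[1L] - ms[2L]) / (ms[1L] + (k0 - 1) * ms[2L])
  expect_equal(icc, w_sd^2 / (w_sd^2 + i_sd^2), tolerance = 0.05)
})
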