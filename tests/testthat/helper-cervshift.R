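# Shared fixtures: everything is generated in code at test time.

# a minimal two-site cohort config for fast structural tests
tiny_cohort_config <- function(n = c(3L, 3L, 3L), seed = 11L, ...) {
  cohort_config(
    sites = list(
      site_spec("site_a", "dev_x", n, device_shift = c(0, 2)),
      site_spec("site_b", "dev_y", n, device_shift = c(0, -2))),
    seed = seed, ...)
}

# random points on the 3-simplex
rand_simplex <- function(n) {
  x <- matrix(stats::rexp(n * 3L), n, 3L)
  x / rowSums(x)
}

# hand-built stand-in model (identity standardization)
mk_model <- function(W) {
  d <- ncol(W) - 1L
  structure(list(weights = W, center = rep(0, d), scale = rep(1, d),
                 meta = list(seed = NA_integer_)),
            class = "standin_model")
}

# prediction tibble from per-image severity scores: p1 = 0, p2 = score/2, so
# score is exactly the class-index-weighted probability average
pred_tbl <- function(woman_id, score, pred_class = NULL, image_id = NULL) {
  n <- length(score)
  stopifnot(all(score >= 0 & score <= 2))
  p2 <- score / 2
  probs <- cbind(p0 = 1 - p2, p1 = 0, p2 = p2)
  if (is.null(pred_class)) pred_class <- max.col(probs, ties.method = "first") - 1L
  if (is.null(image_id)) image_id <- sprintf("img_%04d", seq_len(n))
  tibble::tibble(image_id = image_id, woman_id = as.character(woman_id),
                 p0 = probs[, 1L], p1 = probs[, 2L], p2 = probs[, 3L],
                 score = score, pred_class = as.integer(pred_class))
}

# scaled-down external cohort: 3 geographies on one rotated, translated device
small_ext_cohort_config <- function(seed = 5L, ...) {
  dev <- c(0, 0, 3)
  mk <- function(site, n, geo)
    site_spec(site, "smartphone_j8", n, geo_shift = geo, device_shift = dev,
              severity_rotation = 55, rotation_axis = 4L)
  cohort_config(
    sites = list(
      mk("Bolivia",  c(12L, 10L, 8L), c(0, 0, 0, 0, 0.4)),
      mk("Kenya",    c(10L, 12L, 8L), c(0, 0, 0, 0, 0, 0.4)),
      mk("Thailand", c(10L, 8L, 8L),  c(0, 0, 0, 0, 0, 0, 0.4))),
    seed = seed, ...)
}

small_experiment_config <- function(master_seed = 7L, n_boot = 30L,
                                    increments = c(0L, 2L, 4L),
                                    ratios = list(c(1L, 1L, 1L), c(2L, 2L, 1L)),
                                    heldout_n_women = 20L, ...) {
  experiment_config(
    seed_cohort_config = default_seed_cohort_config(n_women_per_class = c(40L, 40L, 40L)),
    ext_cohort_config = small_ext_cohort_config(),
    heldout_n_women = heldout_n_women,
    increments = increments, ratios = ratios,
    n_boot = n_boot, master_seed = master_seed, ...)
}

# do two AUROC confidence intervals overlap?
ci_overlap <- function(a, b) a$ci_low <= b$ci_high && b$ci_low <= a$ci_high
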