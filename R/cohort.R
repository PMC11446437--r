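# Synthetic multi-site cohort simulator.
#
# Feature model: each image is a d-dimensional Gaussian "embedding"
#   x = R_device(class_mean) + geo_shift + device_shift + woman_effect + image_noise
# where the class means are equally spaced along a single severity axis
# (dimension 1), the device effect is a translation in dimensions orthogonal
# to the severity axis plus an optional rotation of the severity axis into an
# otherwise signal-free dimension, the geography effect is a small orthogonal
# translation, the woman effect is one Gaussian draw shared by all of a
# woman's images, and image noise is i.i.d. per image.

#' Describe one collection site
#'
#' A site is the unit of geography: it has a name, an image-capture device,
#' per-class enrolment counts and its own (small) geography offset. The device
#' effect has two parts: a translation `device_shift` applied to every image
#' from the device, and an optional rotation of the severity axis
#' (`severity_rotation`, degrees) into dimension `rotation_axis`. The rotation
#' models a device whose embedding expresses disease severity along a
#' different direction than the devices seen in training; a pure translation
#' moves the device cluster without touching the direction that carries the
#' class signal.
#'
#' @param site site name (character scalar).
#' @param device device name (character scalar).
#' @param n_women_per_class integer vector of length 3: number of women to
#'   enrol with true class 0 (normal), 1 (indeterminate), 2 (precancer+).
#' @param geo_shift numeric vector, the geography offset (padded with zeros to
#'   the cohort's feature dimension). Should be small relative to
#'   `device_shift`.
#' @param device_shift numeric vector, the device translation.
#' @param severity_rotation rotation of the severity axis, in degrees.
#' @param rotation_axis index (> 1) of the dimension the severity axis is
#'   rotated into.
#' @return a `site_spec` list.
#' @export
site_spec <- function(site, device, n_women_per_class,
                      geo_shift = numeric(0), device_shift = numeric(0),
                      severity_rotation = 0, rotation_axis = 4L) {
  check_config(is.character(site) && length(site) == 1L, "site must be a single name")
  check_config(is.character(device) && length(device) == 1L, "device must be a single name")
  n <- as.integer(n_women_per_class)
  check_config(length(n) == 3L && all(!is.na(n)) && all(n >= 0L),
               "n_women_per_class must be 3 nonnegative integers")
  check_config(is.numeric(geo_shift) && is.numeric(device_shift),
               "shifts must be numeric vectors")
  check_config(length(severity_rotation) == 1L && abs(severity_rotation) < 90,
               "severity_rotation must be a single angle in (-90, 90) degrees")
  check_config(rotation_axis >= 2L, "rotation_axis must be >= 2")
  structure(list(site = site, device = device, n_women_per_class = n,
                 geo_shift = geo_shift, device_shift = device_shift,
                 severity_rotation = as.numeric(severity_rotation),
                 rotation_axis = as.integer(rotation_axis)),
            class = "site_spec")
}

#' Configure a synthetic cohort
#'
#' @param sites list of [site_spec()] objects.
#' @param images_per_woman probabilities of a woman contributing 1, 2, 3 or 4
#'   repeat images at her visit (must sum to 1).
#' @param class_mean_separation distance between adjacent class means along
#'   the severity axis (feature units).
#' @param within_woman_sd standard deviation of the per-woman random effect
#'   (applied to every dimension, shared by all her images).
#' @param between_image_sd standard deviation of the per-image noise.
#' @param n_features embedding dimension d.
#' @param seed integer seed; the whole cohort is drawn from one stream seeded
#'   here, so identical configs yield byte-identical cohorts.
#' @param confirmed_sites sites whose enrolment guarantees histologically
#'   confirmed >CIN2 disease for every precancer+ woman and where hrHPV is not
#'   used for class adjudication (the "Brazil rule").
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(sites,
                          images_per_woman = c(0.10, 0.45, 0.30, 0.15),
                          class_mean_separation = 1.2,
                          within_woman_sd = 0.7,
                          between_image_sd = 0.25,
                          n_features = 8L,
                          seed = 1L,
                          confirmed_sites = "Brazil") {
  check_config(is.list(sites) && length(sites) >= 1L &&
                 all(vapply(sites, inherits, logical(1), "site_spec")),
               "sites must be a non-empty list of site_spec objects")
  p <- as.numeric(images_per_woman)
  check_config(length(p) == 4L && all(p >= 0) && abs(sum(p) - 1) < 1e-8,
               "images_per_woman must be 4 probabilities summing to 1")
  check_config(class_mean_separation > 0, "class_mean_separation must be > 0")
  check_config(within_woman_sd > 0, "within_woman_sd must be > 0")
  check_config(between_image_sd > 0, "between_image_sd must be > 0")
  d <- as.integer(n_features)
  check_config(d >= 2L, "n_features must be >= 2")
  for (s in sites) {
    check_config(length(s$geo_shift) <= d && length(s$device_shift) <= d,
                 "shift vectors longer than n_features")
    check_config(s$severity_rotation == 0 || s$rotation_axis <= d,
                 "rotation_axis exceeds n_features")
  }
  structure(list(sites = sites, images_per_woman = p,
                 class_mean_separation = class_mean_separation,
                 within_woman_sd = within_woman_sd,
                 between_image_sd = between_image_sd,
                 n_features = d, seed = as.integer(seed),
                 confirmed_sites = confirmed_sites),
            class = "cohort_config")
}

pad_to <- function(v, d) c(v, numeric(d - length(v)))

# class-mean matrix (3 x d) for one site: equally spaced means along the
# severity axis, rotated by the site's device rotation
site_class_means <- function(spec, sep, d) {
  theta <- spec$severity_rotation * pi / 180
  axis <- numeric(d)
  axis[1L] <- cos(theta)
  if (theta != 0)
    axis[spec$rotation_axis] <- axis[spec$rotation_axis] + sin(theta)
  outer(0:2 * sep, axis)
}

# one draw of diagnostic facts consistent with a true class (uses the current
# RNG stream; see generate_diagnostic_facts() for the seeded wrapper)
draw_facts <- function(true_class, site, confirmed_sites) {
  confirmed <- site %in% confirmed_sites
  if (true_class == 2L) {
    if (confirmed) {
      hist <- sample(c("CIN3", "AIS", "cancer"), 1L, prob = c(0.70, 0.10, 0.20))
      return(list(histology = hist, hrhpv = "not_tested", expert_label = "absent"))
    }
    if (sample(c(TRUE, FALSE), 1L, prob = c(0.75, 0.25))) {
      hist <- sample(c("CIN3", "AIS", "cancer"), 1L, prob = c(0.80, 0.05, 0.15))
      hpv <- sample(c("positive", "not_tested"), 1L, prob = c(0.80, 0.20))
      return(list(histology = hist, hrhpv = hpv, expert_label = "absent"))
    }
    return(list(histology = "CIN2", hrhpv = "positive", expert_label = "absent"))
  }
  if (true_class == 1L) {
    if (!confirmed && sample(c(TRUE, FALSE), 1L, prob = c(0.30, 0.70))) {
      return(list(histology = "CIN2", hrhpv = "negative", expert_label = "absent"))
    }
    hist <- sample(c("lt_CIN2", "missing"), 1L, prob = c(0.70, 0.30))
    hpv <- sample(c("negative", "not_tested"), 1L, prob = c(0.50, 0.50))
    return(list(histology = hist, hrhpv = hpv, expert_label = "indeterminate"))
  }
  hist <- sample(c("lt_CIN2", "missing"), 1L, prob = c(0.80, 0.20))
  hpv <- sample(c("positive", "negative", "not_tested"), 1L, prob = c(0.30, 0.50, 0.20))
  list(histology = hist, hrhpv = hpv, expert_label = "normal")
}

#' Draw diagnostic facts consistent with a known true class
#'
#' Inverts the ground-truth delineation rules: given a woman's true ordinal
#' class and her site, draws a (histology, hrHPV, expert review) triple that
#' [assign_ground_truth()] maps back to that class. Precancer+ women receive
#' CIN3/AIS/cancer histology or (outside confirmed sites) CIN2 with positive
#' hrHPV; indeterminate women receive CIN2 with negative hrHPV or sub-CIN2 /
#' missing histology with an "indeterminate" expert review; normal women
#' receive sub-CIN2 / missing histology with a "normal" expert review. At
#' `confirmed_sites` every precancer+ woman is histologically >CIN2 and hrHPV
#' is never used.
#'
#' @param true_class integer in 0:2.
#' @param site site name.
#' @param seed optional integer; if given, the draw is made from a stream
#'   seeded with it (leaving the global RNG untouched).
#' @param confirmed_sites see [cohort_config()].
#' @return list with elements `histology`, `hrhpv`, `expert_label`.
#' @export
generate_diagnostic_facts <- function(true_class, site, seed = NULL,
                                      confirmed_sites = "Brazil") {
  stopifnot(length(true_class) == 1L, true_class %in% 0:2)
  if (is.null(seed)) {
    draw_facts(as.integer(true_class), site, confirmed_sites)
  } else {
    withr::with_seed(as.integer(seed),
                     draw_facts(as.integer(true_class), site, confirmed_sites))
  }
}

#' Generate a synthetic cohort
#'
#' Draws, for each site and class, exactly the configured number of women;
#' each woman receives 1-4 repeat images (counts drawn from
#' `images_per_woman`), diagnostic facts consistent with her true class, and
#' feature vectors built as class mean (possibly device-rotated) + geography
#' shift + device shift + a shared woman effect + per-image noise. The whole
#' cohort comes from a single RNG stream seeded at `config$seed`, iterated in
#' fixed site / class / woman order, so it is fully reproducible.
#'
#' @param config a [cohort_config()].
#' @return an object of class `cervshift_cohort`: a list with tibbles `women`
#'   (woman_id, site, device, true_class, histology, hrhpv, expert_label,
#'   n_images) and `images` (image_id, woman_id, f1..fd), plus the config.
#' @export
generate_cohort <- function(config) {
  check_config(inherits(config, "cohort_config"), "config must be a cohort_config")
  d <- config$n_features
  sep <- config$class_mean_separation

  women_rows <- list()
  image_rows <- list()
  withr::with_seed(config$seed, {
    for (spec in config$sites) {
      geo <- pad_to(spec$geo_shift, d)
      dev <- pad_to(spec$device_shift, d)
      means <- site_class_means(spec, sep, d)
      for (cls in 0:2) {
        n_w <- spec$n_women_per_class[cls + 1L]
        if (n_w == 0L) next
        for (w in seq_len(n_w)) {
          wid <- sprintf("%s_c%d_w%03d", spec$site, cls, w)
          n_img <- sample(1:4, 1L, prob = config$images_per_woman)
          facts <- draw_facts(cls, spec$site, config$confirmed_sites)
          weff <- rnorm(d, sd = config$within_woman_sd)
          base <- means[cls + 1L, ] + geo + dev + weff
          feats <- matrix(rnorm(n_img * d, sd = config$between_image_sd),
                          nrow = n_img, ncol = d, byrow = TRUE)
          feats <- sweep(feats, 2L, base, `+`)
          colnames(feats) <- feature_names(d)
          women_rows[[length(women_rows) + 1L]] <- tibble::tibble(
            woman_id = wid, site = spec$site, device = spec$device,
            true_class = cls, histology = facts$histology,
            hrhpv = facts$hrhpv, expert_label = facts$expert_label,
            n_images = n_img)
          image_rows[[length(image_rows) + 1L]] <- tibble::as_tibble(
            cbind(tibble::tibble(image_id = sprintf("%s_i%d", wid, seq_len(n_img)),
                                 woman_id = wid),
                  tibble::as_tibble(feats)))
        }
      }
    }
  })

  women <- if (length(women_rows)) dplyr::bind_rows(women_rows) else
    tibble::tibble(woman_id = character(), site = character(),
                   device = character(), true_class = integer(),
                   histology = character(), hrhpv = character(),
                   expert_label = character(), n_images = integer())
  images <- if (length(image_rows)) dplyr::bind_rows(image_rows) else
    tibble::as_tibble(setNames(
      c(list(character(), character()), replicate(d, numeric(), simplify = FALSE)),
      c("image_id", "woman_id", feature_names(d))))

  if (nrow(women) > 0L) {
    recovered <- assign_ground_truth(women$histology, women$hrhpv,
                                     women$expert_label, women$site,
                                     confirmed_sites = config$confirmed_sites)
    stopifnot(identical(recovered, as.integer(women$true_class)))
  }
  structure(list(women = women, images = images, config = config),
            class = "cervshift_cohort")
}

#' @export
print.cervshift_cohort <- function(x, ...) {
  cat(sprintf("<cervshift_cohort> %d women, %d images, %d sites, %d features\n",
              nrow(x$women), nrow(x$images),
              length(unique(x$women$site)), x$config$n_features))
  if (nrow(x$women)) {
    tab <- table(x$women$site, factor(x$women$true_class, levels = 0:2))
    print(tab)
  }
  invisible(x)
}

#' Combine cohorts
#'
#' Binds the women and images of several cohorts (e.g. a training pool and an
#' external set) into one. Woman ids must not collide.
#' @param ... `cervshift_cohort` objects.
#' @return a `cervshift_cohort` (keeps the first cohort's config).
#' @export
bind_cohorts <- function(...) {
  xs <- list(...)
  stopifnot(all(vapply(xs, inherits, logical(1), "cervshift_cohort")))
  women <- dplyr::bind_rows(lapply(xs, `[[`, "women"))
  if (anyDuplicated(women$woman_id))
    cs_abort("woman_id collision when binding cohorts", "input")
  structure(list(women = women,
                 images = dplyr::bind_rows(lapply(xs, `[[`, "images")),
                 config = xs[[1L]]$config),
            class = "cervshift_cohort")
}

#' Subset a cohort by woman id
#' @param cohort a `cervshift_cohort`.
#' @param woman_ids character vector of woman ids to keep.
#' @return a `cervshift_cohort` restricted to those women.
#' @export
subset_cohort <- function(cohort, woman_ids) {
  stopifnot(inherits(cohort, "cervshift_cohort"))
  structure(list(women = dplyr::filter(cohort$women, .data$woman_id %in% woman_ids),
                 images = dplyr::filter(cohort$images, .data$woman_id %in% woman_ids),
                 config = cohort$config),
            class = "cervshift_cohort")
}

#' Default configuration of the multi-study training ("seed") cohort
#'
#' Two studies on two legacy devices (cerviscope, DSLR) with balanced class
#' mixes. The devices sit at opposite translations along dimension 2 and read
#' severity along the canonical axis (no rotation).
#'
#' @param n_women_per_class women per class per site (default 250, i.e. 1500
#'   women overall).
#' @param seed cohort seed.
#' @param ... passed on to [cohort_config()].
#' @return a `cohort_config`.
#' @export
default_seed_cohort_config <- function(n_women_per_class = c(250L, 250L, 250L),
                                       seed = 101L, ...) {
  cohort_config(
    sites = list(
      site_spec("seed_study_a", "cerviscope", n_women_per_class,
                device_shift = c(0, 2)),
      site_spec("seed_study_b", "dslr", n_women_per_class,
                device_shift = c(0, -2))),
    seed = seed, ...)
}

#' Default configuration of the external six-country smartphone cohort
#'
#' Six geographies sharing one new smartphone device. Per-site class mixes
#' follow the external validation study's enrolment: referral criteria differ
#' by country, so sites contribute very different class mixes (one site
#' contributes only histologically confirmed >CIN2 women), for 580 women in
#' total (204 normal / 157 indeterminate / 219 precancer+). The new device is
#' translated along dimension 3 (far from both legacy devices) and reads
#' severity along an axis rotated 55 degrees into dimension 4 -- a direction
#' carrying no class signal for the legacy devices -- while each geography
#' adds only a small offset in dimensions 5-8.
#'
#' @param seed cohort seed.
#' @param device_shift_magnitude translation of the new device cluster.
#' @param geo_shift_magnitude magnitude of each site's geography offset.
#' @param severity_rotation device rotation of the severity axis, degrees.
#' @param ... passed on to [cohort_config()].
#' @return a `cohort_config`.
#' @export
default_ext_cohort_config <- function(seed = 202L,
                                      device_shift_magnitude = 3,
                                      geo_shift_magnitude = 0.4,
                                      severity_rotation = 55, ...) {
  g <- geo_shift_magnitude
  r2 <- g / sqrt(2)
  dev <- c(0, 0, device_shift_magnitude)
  mk <- function(site, n, geo) {
    site_spec(site, "smartphone_j8", n, geo_shift = geo, device_shift = dev,
              severity_rotation = severity_rotation, rotation_axis = 4L)
  }
  cohort_config(
    sites = list(
      mk("Bolivia",     c(40L,  33L,  15L),  c(0, 0, 0, 0, g)),
      mk("Brazil",      c(0L,   0L,   154L), c(0, 0, 0, 0, 0, g)),
      mk("Cameroon",    c(85L,  13L,  2L),   c(0, 0, 0, 0, 0, 0, g)),
      mk("El Salvador", c(49L,  0L,   21L),  c(0, 0, 0, 0, 0, 0, 0, g)),
      mk("Kenya",       c(0L,   109L, 13L),  c(0, 0, 0, 0, r2, r2)),
      mk("Thailand",    c(30L,  2L,   14L),  c(0, 0, 0, 0, 0, 0, r2, r2))),
    seed = seed, ...)
}
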