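# Experiment orchestration: the three-run device-vs-geography heterogeneity
# comparison, the ratio-controlled incremental-retraining saturation study
# (with catastrophic-forgetting check), the model-comparison image panel, and
# a quantitative heterogeneity projection.

DEFAULT_INCREMENTS <- c(0L, 5L, 13L, 16L, 18L, 21L, 23L, 26L, 28L,
                        41L, 45L, 50L, 55L, 60L, 65L, 70L)

#' Configure the experiment suites
#'
#' One `master_seed` drives every randomized stage (cohort generation, splits,
#' balancing draws, held-out selection, increment sampling, bootstraps) via
#' fixed [sub_seed()] offsets, so the full pipeline is reproducible from a
#' single integer. The seeds stored inside the two cohort configs are
#' overridden with master-derived sub-seeds at run time.
#'
#' @param seed_cohort_config cohort config of the multi-study training set
#'   (default [default_seed_cohort_config()]).
#' @param ext_cohort_config cohort config of the external new-device set
#'   (default [default_ext_cohort_config()]).
#' @param seed_test_frac fraction of training-cohort women held out as its
#'   internal test set (stratified by site and class).
#' @param heldout_n_women size of the common, held-aside external test set.
#' @param heldout_geography external geography held out entirely in run (iii)
#'   of the heterogeneity suite.
#' @param increments strictly increasing values of n, the per-unit number of
#'   women added per ratio step (n = number of precancer+ women added when the
#'   ratio's third entry is 1); must start at the out-of-the-box point 0 to
#'   anchor the curve.
#' @param ratios list of integer triples N:I:P controlling the class mix of
#'   added women.
#' @param train_balance N:I:P woman-level balance applied to the training
#'   cohort before every fit (the balancing used in the original model
#'   development), or NULL for none.
#' @param n_boot bootstrap resamples for every AUROC CI.
#' @param master_seed single integer seed for the whole pipeline.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(seed_cohort_config = default_seed_cohort_config(),
                              ext_cohort_config = default_ext_cohort_config(),
                              seed_test_frac = 0.3,
                              heldout_n_women = 230L,
                              heldout_geography = "Bolivia",
                              increments = DEFAULT_INCREMENTS,
                              ratios = list(c(1L, 1L, 1L), c(2L, 2L, 1L)),
                              train_balance = c(2L, 2L, 1L),
                              n_boot = 1000L,
                              master_seed = 42L) {
  check_config(inherits(seed_cohort_config, "cohort_config") &&
                 inherits(ext_cohort_config, "cohort_config"),
               "cohort configs must be cohort_config objects")
  check_config(seed_test_frac > 0 && seed_test_frac < 1,
               "seed_test_frac must be in (0, 1)")
  increments <- as.integer(increments)
  check_config(length(increments) >= 1L && all(increments >= 0L) &&
                 all(diff(increments) > 0),
               "increments must be strictly increasing and nonnegative")
  check_config(increments[1L] == 0L,
               "increments must start at 0 (the out-of-the-box anchor)")
  check_config(is.list(ratios) && length(ratios) >= 1L &&
                 all(vapply(ratios, function(r) length(r) == 3L && all(r >= 0L) &&
                              sum(r) > 0L, logical(1))),
               "each ratio must be 3 nonnegative integers")
  structure(list(seed_cohort_config = seed_cohort_config,
                 ext_cohort_config = ext_cohort_config,
                 seed_test_frac = seed_test_frac,
                 heldout_n_women = as.integer(heldout_n_women),
                 heldout_geography = heldout_geography,
                 increments = increments,
                 ratios = lapply(ratios, as.integer),
                 train_balance = if (is.null(train_balance)) NULL else
                   as.integer(train_balance),
                 n_boot = as.integer(n_boot),
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

# per-image labels of a cohort
cohort_image_labels <- function(cohort) {
  as.integer(cohort$women$true_class[match(cohort$images$woman_id,
                                           cohort$women$woman_id)])
}

# stratified (site x class) woman-level split of a cohort
split_cohort <- function(cohort, test_frac, seed) {
  w <- cohort$women
  test_ids <- withr::with_seed(seed, {
    unlist(lapply(split(w$woman_id, interaction(w$site, w$true_class, drop = TRUE)),
                  function(ids) {
                    ids <- sort(ids)
                    k <- round(length(ids) * test_frac)
                    if (k == 0L) return(character(0))
                    ids[sample.int(length(ids), k)]
                  }), use.names = FALSE)
  })
  list(train = subset_cohort(cohort, setdiff(w$woman_id, test_ids)),
       test = subset_cohort(cohort, test_ids))
}

# largest-remainder proportional allocation of `total` over groups with
# availabilities `avail`, capped at `caps`
allocate_proportional <- function(avail, total, caps = avail) {
  stopifnot(total <= sum(caps))
  share <- if (sum(avail) > 0) avail / sum(avail) else rep(0, length(avail))
  alloc <- pmin(floor(share * total), caps)
  while (sum(alloc) < total) {
    room <- caps - alloc
    frac <- share * total - floor(share * total)
    frac[room <= 0] <- -Inf
    if (all(!is.finite(frac))) break
    k <- which.max(frac)
    alloc[k] <- alloc[k] + 1L
    share[k] <- 0  # consumed its remainder
  }
  # top up greedily if remainders were exhausted
  while (sum(alloc) < total) {
    room <- caps - alloc
    k <- which.max(room)
    if (room[k] <= 0) break
    alloc[k] <- alloc[k] + 1L
  }
  as.integer(alloc)
}

#' Select the common held-aside external test set
#'
#' Draws `n_heldout` women from the external cohort, stratified by site and
#' class proportionally to availability, while *reserving* enough women of
#' each class outside the held-out set to cover the largest retraining
#' increment under every ratio. (With the default external cohort, 230
#' held-out women and increments up to n = 70, the reserve binds: 140 normal
#' and 140 indeterminate women must stay in the pool, which forces the
#' held-out class mix.)
#'
#' @param ext_cohort the external `cervshift_cohort`.
#' @param n_heldout number of women to hold out.
#' @param increments,ratios as in [experiment_config()]; used to size the
#'   per-class reserve `max(ratio_c * max(increments))`.
#' @param seed integer seed for the draw.
#' @return character vector of held-out woman ids.
#' @export
select_heldout <- function(ext_cohort, n_heldout, increments, ratios, seed) {
  w <- ext_cohort$women
  n_max <- max(increments)
  reserve <- vapply(1:3, function(k)
    max(vapply(ratios, function(r) r[k] * n_max, numeric(1))), numeric(1))
  avail <- vapply(0:2, function(k) sum(w$true_class == k), numeric(1))
  caps <- avail - reserve
  deficient <- which(caps < 0)
  if (length(deficient) > 0L)
    cs_abort(sprintf(
      "external pool cannot cover the largest increment for class %s (%s): need %d women, have %d",
      deficient[1L] - 1L, names(class_labels())[deficient[1L]],
      as.integer(reserve[deficient[1L]]), as.integer(avail[deficient[1L]])),
      "sampling")
  if (sum(caps) < n_heldout)
    cs_abort(sprintf(
      "cannot hold out %d women while reserving %s per class: only %d available",
      n_heldout, paste(as.integer(reserve), collapse = "/"), as.integer(sum(caps))),
      "sampling")
  per_class <- allocate_proportional(avail, n_heldout, caps)
  withr::with_seed(as.integer(seed), {
    unlist(lapply(0:2, function(k) {
      if (per_class[k + 1L] == 0L) return(character(0))
      cls_w <- w[w$true_class == k, , drop = FALSE]
      cells <- split(cls_w$woman_id, cls_w$site)
      cell_avail <- vapply(cells, length, numeric(1))
      cell_alloc <- allocate_proportional(cell_avail, per_class[k + 1L])
      unlist(lapply(seq_along(cells), function(j) {
        if (cell_alloc[j] == 0L) return(character(0))
        ids <- sort(cells[[j]])
        ids[sample.int(length(ids), cell_alloc[j])]
      }), use.names = FALSE)
    }), use.names = FALSE)
  })
}

# apply the fixed training-cohort balance once (same draw as the base model)
balanced_train_ids <- function(train_cohort, train_balance, seed) {
  if (is.null(train_balance)) return(train_cohort$women$woman_id)
  wc <- setNames(as.integer(train_cohort$women$true_class),
                 train_cohort$women$woman_id)
  wc <- wc[sort(names(wc))]
  withr::with_seed(seed, balance_women(wc, train_balance))
}

train_on_cohort <- function(cohort) {
  train_standin(cohort$images, cohort_image_labels(cohort),
                woman_id = cohort$images$woman_id)
}

eval_pair <- function(model, test_cohort, n_boot, seed, repeatability = TRUE) {
  preds <- predict_cohort(model, test_cohort)
  out <- list(metrics = evaluate_predictions(preds, test_cohort$women,
                                             n_boot = n_boot, seed = seed),
              predictions = preds)
  if (repeatability) out$repeatability <- repeatability_report(preds)
  out
}

experiment_cohorts <- function(config) {
  sc <- config$seed_cohort_config
  ec <- config$ext_cohort_config
  sc$seed <- sub_seed(config$master_seed, 1L)
  ec$seed <- sub_seed(config$master_seed, 2L)
  list(seed = generate_cohort(sc), ext = generate_cohort(ec))
}

#' Run the three-run heterogeneity comparison
#'
#' Quantifies how much a device change hurts the classifier compared to a
#' geography change, with three model runs:
#'
#' * **(i)** train on the training-cohort's train split, test on its held-out
#'   split (same devices, same geographies: the internal baseline);
#' * **(ii)** apply that same model out of the box to the full external
#'   cohort (new device: device-shift stress test);
#' * **(iii)** retrain on the train split plus all external images except one
#'   held-out geography, and test on that geography (new geography, device now
#'   represented in training: geography stress test).
#'
#' Each run yields a classification [evaluate_predictions()] report and a
#' [repeatability_report()].
#'
#' @param config an [experiment_config()].
#' @return object of class `heterogeneity_suite`: list `runs` with elements
#'   `seed_test`, `ext_oob`, `heldout_geo` (each: metrics, repeatability,
#'   predictions), the two fitted models, and the cohorts used.
#' @export
run_heterogeneity_suite <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  ms <- config$master_seed
  co <- experiment_cohorts(config)
  if (length(unique(co$seed$women$device)) < 2L)
    cs_abort("training cohort must span at least 2 devices", "config")
  if (!(config$heldout_geography %in% co$ext$women$site))
    cs_abort(sprintf("held-out geography '%s' absent from the external cohort",
                     config$heldout_geography), "config")

  sp <- split_cohort(co$seed, config$seed_test_frac, sub_seed(ms, 3L))
  train_bal <- subset_cohort(sp$train,
                             balanced_train_ids(sp$train, config$train_balance,
                                                sub_seed(ms, 4L)))
  base_model <- train_on_cohort(train_bal)

  ext_rest <- subset_cohort(co$ext, co$ext$women$woman_id[
    co$ext$women$site != config$heldout_geography])
  ext_holdout_geo <- subset_cohort(co$ext, co$ext$women$woman_id[
    co$ext$women$site == config$heldout_geography])

  combined <- bind_cohorts(sp$train, ext_rest)
  comb_bal <- subset_cohort(combined,
                            balanced_train_ids(combined, config$train_balance,
                                               sub_seed(ms, 41L)))
  geo_model <- train_on_cohort(comb_bal)

  runs <- list(
    seed_test = eval_pair(base_model, sp$test, config$n_boot, sub_seed(ms, 61L)),
    ext_oob = eval_pair(base_model, co$ext, config$n_boot, sub_seed(ms, 62L)),
    heldout_geo = eval_pair(geo_model, ext_holdout_geo, config$n_boot,
                            sub_seed(ms, 63L)))
  structure(list(runs = runs,
                 models = list(base = base_model, geo_retrained = geo_model),
                 seed_test_ids = sp$test$women$woman_id,
                 config = config),
            class = "heterogeneity_suite")
}

#' @export
print.heterogeneity_suite <- function(x, ...) {
  cat("<heterogeneity_suite>\n")
  labs <- c(seed_test = "(i) internal test, training devices",
            ext_oob = "(ii) out-of-the-box, new device",
            heldout_geo = "(iii) retrained, held-out geography")
  for (k in names(x$runs)) {
    m <- x$runs[[k]]$metrics
    r <- x$runs[[k]]$repeatability
    cat(sprintf(" %-38s AUROC N %.3f / P+ %.3f, LoA width %.3f\n",
                labs[[k]], m$auroc_normal$auc, m$auroc_precancer$auc,
                r$loa_width))
  }
  invisible(x)
}

#' Run the ratio-controlled incremental-retraining study
#'
#' Starting from the class-balanced training cohort, incrementally adds
#' external new-device women at each configured N:I:P ratio, retrains the
#' stand-in classifier on the combined set at every increment, and evaluates
#' each model on (a) the fixed, common held-aside external test set
#' (classification + repeatability) and (b) the fixed internal test split of
#' the training cohort (classification only -- the catastrophic-forgetting
#' check). Within each ratio the increment selections are *nested*: the women
#' added at increment j contain those added at increment j-1, drawn from one
#' seeded per-class permutation of the pool, so the curve reflects progressive
#' data addition rather than resampling noise. Increment n adds
#' `ratio[c] * n` women of class c.
#'
#' @param config an [experiment_config()].
#' @return object of class `retrain_curve`: `curve` (one tibble row per ratio
#'   x increment with flattened metrics, list-columns of full reports and of
#'   added woman ids), `heldout_ids`, `seed_test_ids`, `base_model`, `config`.
#' @export
run_incremental_retraining <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  ms <- config$master_seed
  co <- experiment_cohorts(config)
  sp <- split_cohort(co$seed, config$seed_test_frac, sub_seed(ms, 3L))
  train_bal <- subset_cohort(sp$train,
                             balanced_train_ids(sp$train, config$train_balance,
                                                sub_seed(ms, 4L)))

  heldout_ids <- select_heldout(co$ext, config$heldout_n_women,
                                config$increments, config$ratios,
                                sub_seed(ms, 5L))
  ext_heldout <- subset_cohort(co$ext, heldout_ids)
  pool <- subset_cohort(co$ext, setdiff(co$ext$women$woman_id, heldout_ids))

  pool_by_class <- lapply(0:2, function(k)
    sort(pool$women$woman_id[pool$women$true_class == k]))
  pool_avail <- vapply(pool_by_class, length, integer(1))

  rows <- list()
  for (ridx in seq_along(config$ratios)) {
    r <- config$ratios[[ridx]]
    ratio_lab <- paste(r, collapse = ":")
    perms <- withr::with_seed(sub_seed(ms, 50L + ridx), {
      lapply(pool_by_class, function(ids) ids[sample.int(length(ids))])
    })
    need_max <- r * max(config$increments)
    short <- which(need_max > pool_avail)
    if (length(short) > 0L)
      cs_abort(sprintf(
        "pool has too few %s women for ratio %s at n = %d: need %d, have %d",
        names(class_labels())[short[1L]], ratio_lab, max(config$increments),
        need_max[short[1L]], pool_avail[short[1L]]), "sampling")

    for (iidx in seq_along(config$increments)) {
      n <- config$increments[iidx]
      added <- unlist(lapply(1:3, function(k) head(perms[[k]], r[k] * n)),
                      use.names = FALSE)
      train_cohort <- if (length(added) == 0L) train_bal else
        bind_cohorts(train_bal, subset_cohort(pool, added))
      model <- train_on_cohort(train_cohort)
      es <- sub_seed(ms, 2000L + 100L * ridx + iidx)
      ev_ext <- eval_pair(model, ext_heldout, config$n_boot, es)
      ev_seed <- eval_pair(model, sp$test, config$n_boot, sub_seed(es, 1L),
                           repeatability = FALSE)
      me <- ev_ext$metrics; re <- ev_ext$repeatability; msd <- ev_seed$metrics
      rows[[length(rows) + 1L]] <- tibble::tibble(
        ratio = ratio_lab,
        n_added = n,
        n_normal_added = r[1L] * n,
        n_indeterminate_added = r[2L] * n,
        n_precancer_added = r[3L] * n,
        women_added_total = sum(r) * n,
        auroc_normal_ext = me$auroc_normal$auc,
        auroc_normal_ext_lo = me$auroc_normal$ci_low,
        auroc_normal_ext_hi = me$auroc_normal$ci_high,
        auroc_precancer_ext = me$auroc_precancer$auc,
        auroc_precancer_ext_lo = me$auroc_precancer$ci_low,
        auroc_precancer_ext_hi = me$auroc_precancer$ci_high,
        pct_extreme_mis_ext = me$pct_extreme_mis,
        pct_total_mis_ext = me$pct_total_mis,
        pct_extreme_dis_ext = re$pct_extreme_disagreement,
        loa_width_ext = re$loa_width,
        loa_half_width_ext = re$loa_half_width,
        auroc_normal_seed = msd$auroc_normal$auc,
        auroc_normal_seed_lo = msd$auroc_normal$ci_low,
        auroc_normal_seed_hi = msd$auroc_normal$ci_high,
        auroc_precancer_seed = msd$auroc_precancer$auc,
        auroc_precancer_seed_lo = msd$auroc_precancer$ci_low,
        auroc_precancer_seed_hi = msd$auroc_precancer$ci_high,
        pct_extreme_mis_seed = msd$pct_extreme_mis,
        pct_total_mis_seed = msd$pct_total_mis,
        report_ext = list(me),
        report_seed = list(msd),
        repeat_ext = list(re),
        added_ids = list(sort(added)))
    }
  }
  structure(list(curve = dplyr::bind_rows(rows),
                 heldout_ids = sort(heldout_ids),
                 seed_test_ids = sort(sp$test$women$woman_id),
                 base_model = train_on_cohort(train_bal),
                 config = config),
            class = "retrain_curve")
}

#' @export
print.retrain_curve <- function(x, ...) {
  cat(sprintf("<retrain_curve> %d increments x %d ratios, %d held-out external women\n",
              length(x$config$increments), length(x$config$ratios),
              length(x$heldout_ids)))
  print(x$curve[, c("ratio", "n_added", "women_added_total",
                    "auroc_normal_ext", "auroc_precancer_ext",
                    "pct_total_mis_ext", "loa_width_ext",
                    "auroc_precancer_seed")], n = nrow(x$curve))
  invisible(x)
}

#' Smallest increment reaching the curve's plateau
#'
#' The plateau point is reported as the smallest n whose metric value comes
#' within `tol` of the maximum over the whole curve (saturation is gradual;
#' this is a simple, reproducible summary of where it sets in).
#'
#' @param retrain a `retrain_curve` (or its `curve` tibble).
#' @param metric curve column to summarize.
#' @param tol closeness to the curve maximum.
#' @return tibble with one row per ratio: plateau_n and plateau_value.
#' @export
plateau_increment <- function(retrain, metric = "auroc_precancer_ext", tol = 0.01) {
  curve <- if (inherits(retrain, "retrain_curve")) retrain$curve else retrain
  stopifnot(metric %in% names(curve))
  dplyr::summarise(
    dplyr::group_by(curve, .data$ratio),
    plateau_n = .data$n_added[which(.data[[metric]] >= max(.data[[metric]]) - tol)[1L]],
    plateau_value = .data[[metric]][which(.data$n_added == .data$plateau_n[1L])[1L]],
    .groups = "drop")
}

#' Catastrophic-forgetting summary
#'
#' For each ratio, the change in internal (training-distribution) test AUROC
#' between the out-of-the-box model (n = 0) and the largest increment. A
#' model free of catastrophic forgetting keeps these drops small.
#'
#' @param retrain a `retrain_curve`.
#' @return tibble with one row per ratio: AUROC at n = 0 and n = max and the
#'   drops, for both one-vs-rest AUROCs.
#' @export
forgetting_check <- function(retrain) {
  curve <- if (inherits(retrain, "retrain_curve")) retrain$curve else retrain
  dplyr::summarise(
    dplyr::group_by(curve, .data$ratio),
    n_max = max(.data$n_added),
    auroc_normal_seed_at0 = .data$auroc_normal_seed[.data$n_added == 0L][1L],
    auroc_normal_seed_atmax = .data$auroc_normal_seed[.data$n_added == max(.data$n_added)][1L],
    auroc_precancer_seed_at0 = .data$auroc_precancer_seed[.data$n_added == 0L][1L],
    auroc_precancer_seed_atmax = .data$auroc_precancer_seed[.data$n_added == max(.data$n_added)][1L],
    drop_normal = .data$auroc_normal_seed_at0 - .data$auroc_normal_seed_atmax,
    drop_precancer = .data$auroc_precancer_seed_at0 - .data$auroc_precancer_seed_atmax,
    .groups = "drop")
}

#' Model-comparison image panel
#'
#' For a set of models evaluated on the same images, computes each image's
#' severity score under every model and the across-model mean score, orders
#' images by increasing mean score within each true class, and draws a
#' quantile-stratified random selection of `per_class` images per class that
#' preserves the mean-score distribution (the ordered images are cut into
#' `per_class` equal-count strata and one image is drawn per stratum).
#'
#' @param models named list of `standin_model` objects (>= 1).
#' @param images images tibble (`image_id`, `f1..fd`).
#' @param truth integer vector of true classes, one per image row.
#' @param per_class images to select per class (default 20); must not exceed
#'   the number of images available in any represented class. If it equals
#'   the class size, the full sorted panel is returned for that class.
#' @param seed seed for the stratified draw.
#' @return list with `panel` (tibble image_id, true_class, mean_score,
#'   panel_rank) and `predictions` (long tibble image_id, model, score,
#'   pred_class for the selected images).
#' @export
model_panel <- function(models, images, truth, per_class = 20L, seed = 1L) {
  stopifnot(is.list(models), length(models) >= 1L)
  if (is.null(names(models)) || any(names(models) == ""))
    names(models) <- sprintf("model_%02d", seq_along(models))
  truth <- as.integer(truth)
  stopifnot(length(truth) == nrow(images))

  preds <- dplyr::bind_rows(lapply(names(models), function(nm) {
    p <- predict_standin(models[[nm]], images)
    tibble::tibble(image_id = p$image_id, model = nm,
                   score = p$score, pred_class = p$pred_class)
  }))
  mean_scores <- tapply(preds$score, preds$image_id, mean)
  info <- tibble::tibble(image_id = images$image_id, true_class = truth,
                         mean_score = as.numeric(mean_scores[images$image_id]))

  panel <- dplyr::bind_rows(lapply(sort(unique(truth)), function(k) {
    cls <- info[info$true_class == k, , drop = FALSE]
    cls <- cls[order(cls$mean_score, cls$image_id), , drop = FALSE]
    if (per_class > nrow(cls))
      cs_abort(sprintf("per_class = %d exceeds the %d images of class %d",
                       per_class, nrow(cls), k), "sampling")
    if (per_class == nrow(cls)) {
      sel <- seq_len(nrow(cls))
    } else {
      strata <- as.integer(cut(seq_len(nrow(cls)), breaks = per_class,
                               labels = FALSE))
      sel <- withr::with_seed(sub_seed(seed, k), {
        vapply(seq_len(per_class), function(s) {
          cand <- which(strata == s)
          cand[sample.int(length(cand), 1L)]
        }, integer(1))
      })
    }
    out <- cls[sort(sel), , drop = FALSE]
    out$panel_rank <- seq_len(nrow(out))
    out
  }))
  list(panel = panel,
       predictions = preds[preds$image_id %in% panel$image_id, , drop = FALSE])
}

#' Two-dimensional heterogeneity projection with separation statistics
#'
#' Projects image features to two dimensions (by default the first two
#' principal components -- a variance-preserving linear projection) and
#' quantifies, for each grouping axis (e.g. device, geography), how separated
#' the groups are in the projection via the mean silhouette width
#' ([cluster::silhouette()]): near 1 for well-separated clusters, near 0 when
#' the groups are interleaved.
#'
#' @param features numeric matrix (images x d) or an images tibble.
#' @param groupings named list (or data frame) of grouping vectors, one per
#'   axis, each of length nrow(features) with >= 2 distinct values.
#' @param max_n if more rows than this, a seeded subsample of rows is used
#'   (silhouette distances are quadratic in n).
#' @param seed seed for the subsample.
#' @return list with `embedding` (tibble dim1, dim2 plus the grouping
#'   columns) and `separation` (named numeric, one mean silhouette width per
#'   grouping axis).
#' @export
heterogeneity_projection <- function(features, groupings, max_n = 2000L,
                                     seed = 1L) {
  X <- if (is.data.frame(features)) feature_matrix(features) else as.matrix(features)
  groupings <- as.list(groupings)
  stopifnot(length(groupings) >= 1L, !is.null(names(groupings)))
  for (nm in names(groupings)) {
    stopifnot(length(groupings[[nm]]) == nrow(X))
    if (length(unique(groupings[[nm]])) < 2L)
      cs_abort(sprintf("grouping '%s' has a single group: separation undefined", nm),
               "undefined_metric")
  }
  if (nrow(X) > max_n) {
    keep <- withr::with_seed(as.integer(seed), sort(sample.int(nrow(X), max_n)))
    X <- X[keep, , drop = FALSE]
    groupings <- lapply(groupings, `[`, keep)
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = 2L)
  emb <- pc$x[, 1:2, drop = FALSE]
  dd <- dist(emb)
  separation <- vapply(groupings, function(g) {
    g <- as.integer(factor(g))
    if (length(unique(g)) < 2L) return(NA_real_)
    mean(cluster::silhouette(g, dd)[, "sil_width"])
  }, numeric(1))
  embedding <- tibble::as_tibble(
    c(list(dim1 = emb[, 1L], dim2 = emb[, 2L]), groupings))
  list(embedding = embedding, separation = separation)
}
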