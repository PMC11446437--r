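# Delimited-text and JSON interfaces: cohorts as women.csv / images.csv with a
# class-label sidecar, predictions as predictions.csv, models and metric
# reports as JSON.

#' Write a cohort to a directory
#'
#' Writes `women.csv` (woman_id, site, device, true_class, histology, hrhpv,
#' expert_label), `images.csv` (image_id, woman_id, f1..fd) and a sidecar
#' `classes.json` mapping the integer class codes to their names. UTF-8,
#' header row, no row names.
#'
#' @param cohort a `cervshift_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cervshift_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- cohort$women
  w$n_images <- NULL
  write.csv(w, file.path(dir, "women.csv"), row.names = FALSE, fileEncoding = "UTF-8")
  write.csv(cohort$images, file.path(dir, "images.csv"), row.names = FALSE,
            fileEncoding = "UTF-8")
  jsonlite::write_json(as.list(setNames(names(class_labels()),
                                        as.character(class_labels()))),
                       file.path(dir, "classes.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory containing `women.csv` and `images.csv`.
#' @return a `cervshift_cohort` (config slot empty).
#' @export
read_cohort <- function(dir) {
  women <- tibble::as_tibble(read.csv(file.path(dir, "women.csv"),
                                      stringsAsFactors = FALSE))
  images <- tibble::as_tibble(read.csv(file.path(dir, "images.csv"),
                                       stringsAsFactors = FALSE))
  women$true_class <- as.integer(women$true_class)
  tab <- table(images$woman_id)
  women$n_images <- as.integer(tab[women$woman_id])
  structure(list(women = women, images = images, config = NULL),
            class = "cervshift_cohort")
}

#' Write / read a predictions table
#' @param predictions tibble from [predict_standin()].
#' @param path CSV path.
#' @return the path (write) or the predictions tibble (read).
#' @export
write_predictions <- function(predictions, path) {
  write.csv(predictions[, c("image_id", "woman_id", "p0", "p1", "p2",
                            "score", "pred_class")],
            path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  out <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  out$pred_class <- as.integer(out$pred_class)
  out
}

#' Serialize / deserialize a stand-in model as JSON
#' @param model a `standin_model`.
#' @param path JSON path.
#' @return the path (write) or a `standin_model` (read).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "standin_model"))
  obj <- list(weights = unname(as.data.frame(model$weights)),
              center = as.numeric(model$center),
              scale = as.numeric(model$scale),
              meta = model$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- as.matrix(obj$weights)
  d <- ncol(W) - 1L
  dimnames(W) <- list(names(class_labels()), c("(intercept)", feature_names(d)))
  meta <- obj$meta
  meta$balance_ratio <- if (is.null(meta$balance_ratio)) NULL else
    as.integer(meta$balance_ratio)
  structure(list(weights = W, center = as.numeric(obj$center),
                 scale = as.numeric(obj$scale), meta = meta),
            class = "standin_model")
}

# plain-list views of report objects, for JSON export and byte-identity checks
report_to_list <- function(x) UseMethod("report_to_list")

#' @export
report_to_list.metrics_report <- function(x) {
  list(auroc_normal = x$auroc_normal[c("auc", "ci_low", "ci_high")],
       auroc_precancer = x$auroc_precancer[c("auc", "ci_low", "ci_high")],
       confusion = unname(lapply(seq_len(3L), function(i) as.integer(x$confusion[i, ]))),
       pct_extreme_mis = x$pct_extreme_mis,
       pct_total_mis = x$pct_total_mis,
       n_images = x$n_images, n_women = x$n_women)
}

#' @export
report_to_list.repeatability_report <- function(x) {
  list(loa_center = x$loa_center, loa_low = x$loa_low, loa_high = x$loa_high,
       loa_width = x$loa_width, loa_half_width = x$loa_half_width,
       pct_extreme_disagreement = x$pct_extreme_disagreement,
       n_women_evaluable = x$n_women_evaluable,
       n_women_single_image = x$n_women_single_image)
}

#' @export
report_to_list.heterogeneity_suite <- function(x) {
  lapply(x$runs, function(r) list(metrics = report_to_list(r$metrics),
                                  repeatability = report_to_list(r$repeatability)))
}

#' @export
report_to_list.retrain_curve <- function(x) {
  curve <- x$curve
  scalar_cols <- names(curve)[!vapply(curve, is.list, logical(1))]
  list(curve = as.list(curve[, scalar_cols]),
       heldout_ids = x$heldout_ids,
       seed_test_ids = x$seed_test_ids)
}

#' Write a metrics / repeatability / experiment report as JSON
#'
#' @param report a `metrics_report`, `repeatability_report`,
#'   `heterogeneity_suite` or `retrain_curve`.
#' @param path JSON path.
#' @return the path, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read a cohort config from YAML
#'
#' Expects top-level keys matching [cohort_config()] arguments, with `sites`
#' a list of [site_spec()] argument sets.
#'
#' @param path YAML file path.
#' @return a `cohort_config`.
#' @export
read_cohort_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  check_config(!is.null(y$sites), "YAML config needs a 'sites' list")
  sites <- lapply(y$sites, function(s) do.call(site_spec, s))
  y$sites <- NULL
  do.call(cohort_config, c(list(sites = sites), y))
}
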