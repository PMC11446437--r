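# Ground-truth delineation rules and site-by-class dataset bookkeeping.

HISTOLOGY_LEVELS <- c("lt_CIN2", "missing", "CIN2", "CIN3", "AIS", "cancer")
HRHPV_LEVELS <- c("positive", "negative", "not_tested")
EXPERT_LEVELS <- c("normal", "indeterminate", "absent")

#' Class labels of the ordinal ground truth
#'
#' @return named integer vector mapping label names to ordinal codes
#'   (normal = 0 < indeterminate = 1 < precancer+ = 2).
#' @export
class_labels <- function() c(normal = 0L, indeterminate = 1L, `precancer+` = 2L)

#' Assign ordinal ground truth from diagnostic facts
#'
#' Encodes the delineation rules used to label each woman (and, by
#' inheritance, each of her images):
#'
#' 1. histology CIN3, AIS or cancer -> precancer+ (2);
#' 2. histology CIN2 at a confirmed site -> precancer+ (at such sites
#'    enrolment guarantees histologically confirmed disease and hrHPV is not
#'    used for adjudication);
#' 3. histology CIN2 elsewhere -> adjudicated by hrHPV: positive ->
#'    precancer+ (2), negative -> indeterminate (1), not tested ->
#'    unresolvable-record error;
#' 4. histology below CIN2 or missing -> the expert-review label decides:
#'    "normal" -> 0, "indeterminate" -> 1, absent -> unresolvable-record
#'    error.
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param histology one of `lt_CIN2, missing, CIN2, CIN3, AIS, cancer`.
#' @param hrhpv one of `positive, negative, not_tested`.
#' @param expert_label one of `normal, indeterminate, absent`.
#' @param site site name (used only to test membership in `confirmed_sites`).
#' @param confirmed_sites sites where the confirmed->precancer+ override
#'   applies (default `"Brazil"`).
#' @return integer vector of classes in 0:2.
#' @export
assign_ground_truth <- function(histology, hrhpv, expert_label, site,
                                confirmed_sites = "Brazil") {
  n <- max(length(histology), length(hrhpv), length(expert_label), length(site))
  histology <- rep_len(as.character(histology), n)
  hrhpv <- rep_len(as.character(hrhpv), n)
  expert_label <- rep_len(as.character(expert_label), n)
  site <- rep_len(as.character(site), n)

  bad <- !(histology %in% HISTOLOGY_LEVELS)
  if (any(bad)) cs_abort(paste0("unknown histology value: ", histology[bad][1L]), "input")
  bad <- !(hrhpv %in% HRHPV_LEVELS)
  if (any(bad)) cs_abort(paste0("unknown hrhpv value: ", hrhpv[bad][1L]), "input")
  bad <- !(expert_label %in% EXPERT_LEVELS)
  if (any(bad)) cs_abort(paste0("unknown expert_label value: ", expert_label[bad][1L]), "input")

  out <- rep(NA_integer_, n)
  confirmed <- site %in% confirmed_sites

  out[histology %in% c("CIN3", "AIS", "cancer")] <- 2L

  cin2 <- histology == "CIN2"
  out[cin2 & confirmed] <- 2L
  out[cin2 & !confirmed & hrhpv == "positive"] <- 2L
  out[cin2 & !confirmed & hrhpv == "negative"] <- 1L
  unresolved <- cin2 & !confirmed & hrhpv == "not_tested"
  if (any(unresolved))
    cs_abort("CIN2 without an hrHPV result outside a confirmed site cannot be classed",
             "unresolvable")

  low <- histology %in% c("lt_CIN2", "missing")
  out[low & expert_label == "normal"] <- 0L
  out[low & expert_label == "indeterminate"] <- 1L
  if (any(low & expert_label == "absent"))
    cs_abort("histology below CIN2 requires an expert-review label", "unresolvable")

  stopifnot(!anyNA(out))
  out
}

#' Summarize a cohort by site and ground-truth class
#'
#' Produces the site-by-class breakdown at both the image and the woman level
#' (every image inherits its woman's class), with row/column margins, grand
#' totals and percentages recomputed as cell / grand total.
#'
#' @param cohort a `cervshift_cohort` (or a list with `women` and `images`
#'   tibbles; `images` only needs `woman_id`).
#' @return object of class `dataset_summary`: a list with `counts` (tibble:
#'   site, class, n_images, n_women, pct_images, pct_women), matrices
#'   `image_matrix` and `woman_matrix` (site x class with TOTAL margins) and
#'   `totals` (n_images, n_women, per-class totals).
#' @export
summarize_dataset <- function(cohort) {
  women <- cohort$women
  images <- cohort$images
  stopifnot(is.data.frame(women), is.data.frame(images))
  sites <- sort(unique(women$site))
  cls <- factor(women$true_class, levels = 0:2)

  w_tab <- table(factor(women$site, levels = sites), cls)
  img_class <- women$true_class[match(images$woman_id, women$woman_id)]
  i_tab <- table(factor(women$site[match(images$woman_id, women$woman_id)], levels = sites),
                 factor(img_class, levels = 0:2))

  n_images <- sum(i_tab)
  n_women <- sum(w_tab)
  counts <- tibble::tibble(
    site = rep(sites, each = 3L),
    class = rep(0:2, times = length(sites)),
    n_images = as.integer(t(i_tab)),
    n_women = as.integer(t(w_tab)))
  counts$pct_images <- if (n_images > 0) 100 * counts$n_images / n_images else 0
  counts$pct_women <- if (n_women > 0) 100 * counts$n_women / n_women else 0

  with_margins <- function(tab) {
    m <- matrix(as.integer(tab), nrow = length(sites), ncol = 3L,
                dimnames = list(sites, names(class_labels())))
    m <- rbind(m, TOTAL = colSums(m))
    cbind(m, TOTAL = rowSums(m))
  }
  im <- with_margins(i_tab)
  wm <- with_margins(w_tab)
  structure(list(counts = counts, image_matrix = im, woman_matrix = wm,
                 totals = list(n_images = n_images, n_women = n_women,
                               images_per_class = setNames(colSums(i_tab[, , drop = FALSE]),
                                                           names(class_labels())),
                               women_per_class = setNames(colSums(w_tab[, , drop = FALSE]),
                                                          names(class_labels())))),
            class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat(sprintf("<dataset_summary> %d images, %d women\n",
              x$totals$n_images, x$totals$n_women))
  cat("image-level counts:\n")
  print(x$image_matrix)
  cat("woman-level counts:\n")
  print(x$woman_matrix)
  invisible(x)
}

#' Published breakdown of the external validation study
#'
#' The per-site, per-class image and woman counts of the six-country external
#' smartphone validation set (580 women, 1669 images), as printed in the
#' study report. Used as bookkeeping input, e.g. to verify that
#' [summarize_dataset()] reproduces the printed grand totals; note that the
#' study report's percentage columns are internally inconsistent with these
#' cell counts, so percentages should always be recomputed as cell / grand
#' total.
#'
#' @return tibble with columns site, class, n_images, n_women.
#' @export
ext_study_counts <- function() {
  tibble::tribble(
    ~site,          ~class, ~n_images, ~n_women,
    "Bolivia",       0L,     140L,      40L,
    "Bolivia",       1L,     118L,      33L,
    "Bolivia",       2L,      59L,      15L,
    "Brazil",        0L,       0L,       0L,
    "Brazil",        1L,       0L,       0L,
    "Brazil",        2L,     410L,     154L,
    "Cameroon",      0L,     231L,      85L,
    "Cameroon",      1L,      33L,      13L,
    "Cameroon",      2L,       2L,       2L,
    "El Salvador",   0L,     130L,      49L,
    "El Salvador",   1L,       0L,       0L,
    "El Salvador",   2L,      56L,      21L,
    "Kenya",         0L,       0L,       0L,
    "Kenya",         1L,     309L,     109L,
    "Kenya",         2L,      36L,      13L,
    "Thailand",      0L,      97L,      30L,
    "Thailand",      1L,       5L,       2L,
    "Thailand",      2L,      43L,      14L)
}

#' Build a cohort skeleton with exact per-cell image and woman counts
#'
#' Constructs a minimal cohort (no features, zero-filled) whose site-by-class
#' image and woman counts match a given counts table exactly -- images are
#' spread over women as evenly as possible. Useful to exercise the
#' bookkeeping on published count tables.
#'
#' @param counts tibble with columns site, class, n_images, n_women
#'   (n_images >= n_women; n_images > 0 requires n_women > 0).
#' @return a `cervshift_cohort` with one zero feature column.
#' @export
cohort_from_counts <- function(counts) {
  stopifnot(all(c("site", "class", "n_images", "n_women") %in% names(counts)))
  check_config(all(counts$n_images >= counts$n_women),
               "each cell needs at least one image per woman")
  check_config(all(counts$n_women > 0 | counts$n_images == 0),
               "images without women in a cell")
  women <- list()
  images <- list()
  for (r in seq_len(nrow(counts))) {
    nw <- counts$n_women[r]
    if (nw == 0L) next
    ni <- counts$n_images[r]
    per <- rep(ni %/% nw, nw)
    extra <- ni %% nw
    if (extra > 0L) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
    wid <- sprintf("%s_c%d_w%03d", counts$site[r], counts$class[r], seq_len(nw))
    women[[r]] <- tibble::tibble(
      woman_id = wid, site = counts$site[r], device = "unknown",
      true_class = counts$class[r], histology = "missing", hrhpv = "not_tested",
      expert_label = "normal", n_images = per)
    images[[r]] <- tibble::tibble(
      image_id = unlist(lapply(seq_len(nw),
                               function(i) sprintf("%s_i%d", wid[i], seq_len(per[i])))),
      woman_id = rep(wid, per), f1 = 0)
  }
  structure(list(women = dplyr::bind_rows(women),
                 images = dplyr::bind_rows(images),
                 config = NULL),
            class = "cervshift_cohort")
}
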