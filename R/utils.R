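# Internal helpers: seed derivation, classed errors, small validators.

#' Derive a reproducible sub-seed from a master seed
#'
#' All randomized stages of the experiment suites draw their own integer seed
#' from the single `master_seed` via this fixed affine-modular scheme, so that
#' one master seed reproduces every table byte for byte while stages stay
#' statistically decoupled.
#'
#' @param master integer master seed.
#' @param k integer stage offset (each pipeline stage uses a fixed offset).
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
sub_seed <- function(master, k) {
  stopifnot(length(master) == 1L, length(k) == 1L, is.finite(master), is.finite(k))
  m <- as.numeric(master) %% 2147483647
  as.integer((m * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

cs_abort <- function(message, class) {
  rlang::abort(message, class = c(paste0("cervshift_error_", class), "cervshift_error"))
}

check_config <- function(ok, message) {
  if (!isTRUE(ok)) cs_abort(message, "config")
  invisible(TRUE)
}

# feature-column names for a d-dimensional cohort
feature_names <- function(d) paste0("f", seq_len(d))

# extract the feature matrix from an images tibble (columns f1..fd)
feature_matrix <- function(images) {
  fcols <- grep("^f[0-9]+$", names(images), value = TRUE)
  if (length(fcols) == 0L) cs_abort("no feature columns (f1..fd) found", "input")
  fcols <- fcols[order(as.integer(sub("^f", "", fcols)))]
  as.matrix(images[, fcols, drop = FALSE])
}
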