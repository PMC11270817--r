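# Light containers used across the package.

#' Construct a sample batch
#'
#' A matrix of configurations (one row per configuration) tagged with
#' its origin (`"md"` for data sampled from a physical state,
#' `"model"` for flow-generated samples), the state of origin, and
#' optional cached quantities.
#'
#' @param coords numeric matrix, one configuration per row.
#' @param origin `"md"` or `"model"`.
#' @param state integer state label of origin (NA for model samples
#'   not tied to a state).
#' @param energy optional cached reduced energies (one per row).
#' @param log_q optional cached model log-densities.
#' @return object of class `sample_batch`.
#' @export
sample_batch <- function(coords, origin = c("md", "model"), state = NA_integer_,
                         energy = NULL, log_q = NULL) {
  origin <- match.arg(origin)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  structure(list(coords = coords, origin = origin,
                 state = as.integer(state),
                 energy = energy, log_q = log_q),
            class = "sample_batch")
}

#' @export
print.sample_batch <- function(x, ...) {
  cat(sprintf("<sample_batch: %d x %d, origin=%s, state=%s>\n",
              nrow(x$coords), ncol(x$coords), x$origin,
              ifelse(is.na(x$state), "-", x$state)))
  invisible(x)
}

# coordinates from either a bare matrix or a sample_batch
batch_coords <- function(batch) {
  if (inherits(batch, "sample_batch")) batch$coords else as.matrix(batch)
}

batch_origin <- function(batch, default = "md") {
  if (inherits(batch, "sample_batch")) batch$origin else default
}

#' Construct a free-energy estimate record
#'
#' @param value reduced free energy (or difference).
#' @param stderr analytic standard error (>= 0).
#' @param estimator one of `"AVMD"`, `"AVBG"`, `"EXPMD"`, `"EXPBG"`,
#'   `"BAR"`, `"MBAR"`.
#' @param split `"T"` (training), `"V"` (validation) or `NA`.
#' @param n_used sample counts that entered the estimate.
#' @param n_dropped number of non-finite work values excluded (model
#'   samples falling outside the state or domain).
#' @return object of class `fe_estimate`.
#' @export
fe_estimate <- function(value, stderr, estimator, split = NA_character_,
                        n_used = NA_integer_, n_dropped = 0L) {
  stopifnot(estimator %in% c("AVMD", "AVBG", "EXPMD", "EXPBG", "BAR", "MBAR"))
  if (is.finite(stderr)) stopifnot(stderr >= 0)
  structure(list(value = value, stderr = stderr, estimator = estimator,
                 split = split, n_used = n_used, n_dropped = n_dropped),
            class = "fe_estimate")
}

#' @export
print.fe_estimate <- function(x, ...) {
  cat(sprintf("%s%s: %.6f +/- %.6f (n=%s)\n", x$estimator,
              ifelse(is.na(x$split), "", paste0("_", x$split)),
              x$value, x$stderr, x$n_used))
  invisible(x)
}
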