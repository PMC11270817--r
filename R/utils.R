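#' Numerically stable log-sum-exp
#'
#' Computes `log(sum(exp(x)))` without overflow. Entries equal to
#' `-Inf` contribute zero weight; if all entries are `-Inf` the result
#' is `-Inf`.
#'
#' @param x numeric vector.
#' @return scalar.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) {
    if (m == -Inf) return(-Inf)
    stop("logsumexp: +Inf or NaN input")
  }
  m + log(sum(exp(x - m)))
}

#' Row-wise log-sum-exp of a matrix
#' @param x numeric matrix; `-Inf` entries allowed.
#' @return vector of length `nrow(x)`.
#' @keywords internal
row_logsumexp <- function(x) {
  m <- row_max(x)
  out <- m + log(rowSums(exp(x - m)))
  out[m == -Inf] <- -Inf
  if (any(is.nan(m))) stop("row_logsumexp: NaN input")
  out
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

sigmoid <- function(x) 1 / (1 + exp(-x))

row_max <- function(x) {
  m <- x[, 1L]
  for (j in seq_len(ncol(x))[-1L]) m <- pmax(m, x[, j])
  m
}

row_softmax <- function(x) {
  e <- exp(x - row_max(x))
  e / rowSums(e)
}

row_cumsum <- function(x) {
  for (j in seq_len(ncol(x))[-1L]) x[, j] <- x[, j] + x[, j - 1L]
  x
}

#' Derive a stage seed from a master seed
#'
#' Seed-splitting rule used throughout the package: every independent
#' source of randomness (sampler chain, parameter initialization,
#' batch shuffling, model-sample draws at each evaluation event, ...)
#' receives `split_seed(master, stage)` where `stage` is a small
#' non-negative integer unique to that consumer. The rule is a fixed
#' affine hash reduced modulo 2^31 - 1 so results are reproducible
#' from a single master seed and seeds remain valid 32-bit integers.
#'
#' @param master integer master seed.
#' @param stage integer stage index (>= 0).
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(master, stage) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.double(master) %% m) * 48271 + as.double(stage) * 16807 + 12345
  as.integer(s %% (m - 1) + 1)
}
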