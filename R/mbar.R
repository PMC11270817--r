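# Multistate Bennett acceptance ratio (MBAR) solver with asymptotic
# covariance.
#
# Given reduced energies u_i(x_n) of every state i evaluated at every
# pooled sample x_n (here: remapped effective potentials built from
# composed flow maps), MBAR solves the self-consistent equations
#
#   f_i = -ln sum_n exp(-u_i(x_n)) / sum_k N_k exp(f_k - u_k(x_n))
#
# whose solutions determine the partition functions up to a common
# multiplicative constant; the gauge is fixed by f_1 = 0.  The
# solver runs damped self-consistent iteration, switches to BFGS on
# the standard convex objective, and polishes with further
# self-consistent sweeps so the returned solution satisfies the
# equations to near machine precision.  `+Inf` energies (zero-weight
# configurations, e.g. remapped images that left the target state)
# are handled exactly.

# log-denominators: log sum_k N_k exp(f_k - u_kn) for each sample
.mbar_logden <- function(u_mat, f, log_N, active) {
  row_logsumexp(sweep(-u_mat[, active, drop = FALSE], 2L,
                      f[active] + log_N[active], "+"))
}

# one self-consistent update of f (gauge-fixed to f[1] = 0)
.mbar_sc <- function(u_mat, f, log_N, active) {
  ld <- .mbar_logden(u_mat, f, log_N, active)
  fn <- -apply(-u_mat - ld, 2L, logsumexp)
  fn - fn[1L]
}

#' Solve the MBAR equations
#'
#' @param u_mat N x K matrix: reduced (remapped) energy of every
#'   state (columns) at every pooled sample (rows); `+Inf` entries
#'   mark zero-weight configurations.  Every row must be finite in
#'   at least one column.
#' @param N_k integer vector of sample counts per state (states with
#'   zero samples are evaluated perturbatively).  `sum(N_k)` must
#'   equal `nrow(u_mat)`.
#' @param tol self-consistency tolerance (default 1e-12 on the
#'   maximum change of any f between sweeps).
#' @param max_iter iteration budget.
#' @return list with `f` (per-state reduced free energies, gauge
#'   `f[1] = 0`), `covariance` (asymptotic K x K covariance of `f`),
#'   `W` (weight matrix) and `residual` (final self-consistency
#'   residual).
#' @export
mbar_solve <- function(u_mat, N_k, tol = 1e-12, max_iter = 10000L) {
  u_mat <- as.matrix(u_mat)
  K <- ncol(u_mat)
  N <- nrow(u_mat)
  stopifnot(K >= 2L, length(N_k) == K, sum(N_k) == N)
  if (any(!is.finite(row_max(-u_mat)))) {
    stop("every sample must have at least one finite energy")
  }
  .mbar_check_connected(u_mat, N_k)
  active <- N_k > 0L
  log_N <- ifelse(active, log(N_k), -Inf)
  f <- numeric(K)
  # stage 1: self-consistent iteration
  for (it in seq_len(50L)) {
    fn <- .mbar_sc(u_mat, f, log_N, active)
    delta <- max(abs(fn - f))
    f <- fn
    if (delta < tol) break
  }
  # stage 2: quasi-Newton polish on the convex objective (active
  # states only; free parameters f_2..f_K among active states)
  if (delta >= tol) {
    act_idx <- which(active)
    free_idx <- setdiff(act_idx, 1L)
    obj <- function(ff) {
      f2 <- f
      f2[free_idx] <- ff
      ld <- .mbar_logden(u_mat, f2, log_N, active)
      sum(ld) - sum(N_k[act_idx] * f2[act_idx])
    }
    grd <- function(ff) {
      f2 <- f
      f2[free_idx] <- ff
      ld <- .mbar_logden(u_mat, f2, log_N, active)
      vapply(free_idx, function(i) {
        N_k[i] * sum(exp(f2[i] - u_mat[, i] - ld)) - N_k[i]
      }, numeric(1))
    }
    if (length(free_idx)) {
      opt <- stats::optim(f[free_idx], obj, grd, method = "BFGS",
                          control = list(maxit = max_iter, reltol = 1e-14))
      f[free_idx] <- opt$par
    }
    # stage 3: final self-consistent sweeps to the requested tolerance
    for (it in seq_len(200L)) {
      fn <- .mbar_sc(u_mat, f, log_N, active)
      delta <- max(abs(fn - f))
      f <- fn
      if (delta < tol) break
    }
  }
  # inactive (zero-sample) states: perturbative evaluation
  if (any(!active)) {
    ld <- .mbar_logden(u_mat, f, log_N, active)
    for (i in which(!active)) f[i] <- -logsumexp(-u_mat[, i] - ld)
    f <- f - f[1L]
  }
  ld <- .mbar_logden(u_mat, f, log_N, active)
  W <- exp(sweep(-u_mat - ld, 2L, f, "+")) # W_ni, sum_n W_ni = 1
  V <- mbar_covariance(u_mat, N_k, f = f, W = W)
  f <- unname(f)
  list(f = f, covariance = V, W = W,
       residual = max(abs(.mbar_sc(u_mat, f, log_N, active) - f)))
}

#' Asymptotic covariance of MBAR free energies
#'
#' The standard large-sample estimator built from the weight matrix
#' `W` (`W_ni = exp(f_i - u_i(x_n)) / sum_k N_k exp(f_k - u_k(x_n))`):
#' with thin SVD `W = U S V^T`,
#' `Theta = V S (I - S V^T diag(N) V S)^+ S V^T`.
#' Variances of differences follow as
#' `var(f_i - f_j) = Theta_ii + Theta_jj - 2 Theta_ij`.
#'
#' @param u_mat,N_k as in [mbar_solve()].
#' @param f solved free energies.
#' @param W optional precomputed weight matrix.
#' @return K x K covariance matrix.
#' @export
mbar_covariance <- function(u_mat, N_k, f, W = NULL) {
  K <- ncol(u_mat)
  active <- N_k > 0L
  log_N <- ifelse(active, log(N_k), -Inf)
  if (is.null(W)) {
    ld <- .mbar_logden(u_mat, f, log_N, active)
    W <- exp(sweep(-u_mat - ld, 2L, f, "+"))
  }
  sv <- svd(W)
  S <- sv$d
  V <- sv$v
  A <- diag(K) - (S * t(V)) %*% (N_k * V) %*% diag(S, K)
  # pseudo-inverse (the gauge direction is a null vector)
  ea <- svd(A)
  pos <- ea$d > max(ea$d) * 1e-10
  Ainv <- ea$v[, pos, drop = FALSE] %*%
    (t(ea$u[, pos, drop = FALSE]) / ea$d[pos])
  Theta <- V %*% diag(S, K) %*% Ainv %*% diag(S, K) %*% t(V)
  (Theta + t(Theta)) / 2
}

# overlap-graph connectivity: states i, j are linked if some sample
# has finite energy in both columns; error names the components
.mbar_check_connected <- function(u_mat, N_k) {
  K <- ncol(u_mat)
  fin <- is.finite(u_mat)
  comp <- seq_len(K)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(K - 1L)) {
    for (j in (i + 1L):K) {
      if (any(fin[, i] & fin[, j])) {
        ri <- find(i); rj <- find(j)
        comp[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(K), find, integer(1))
  if (length(unique(roots)) > 1L) {
    groups <- split(seq_len(K), roots)
    stop("disconnected overlap graph; components: ",
         paste(vapply(groups, function(g) paste0("{", paste(g, collapse = ","), "}"),
                      character(1)), collapse = " "))
  }
  invisible(TRUE)
}

#' Targeted MBAR estimate from per-state maps
#'
#' Builds the full remapped energy matrix `u_{k->i}` for all pairs of
#' states by composing each source state's map with each target
#' state's map through the common base space, pools the physical
#' (MD-origin) samples of all states, and solves the MBAR equations.
#' Model-generated samples and the base distribution itself are not
#' included by default, matching the estimation protocol used
#' throughout the package's convergence studies.
#'
#' @param maps list of K state maps.
#' @param rpots list of K [restricted_potential()] objects.
#' @param batches list of K `sample_batch`es of MD-origin samples
#'   (one per state, in that state's coordinates).
#' @param split `"T"`, `"V"` or `NA`.
#' @return list with `f`, `covariance`, per-pair [fe_estimate()]s in
#'   `pairs` (entry `"i-j"` holds `f_j - f_i`), and the fraction of
#'   remapped evaluations rejected per (k, i) pair.
#' @export
estimate_MBAR <- function(maps, rpots, batches, split = NA_character_) {
  K <- length(maps)
  stopifnot(length(rpots) == K, length(batches) == K, K >= 2L)
  N_k <- vapply(batches, function(b) nrow(batch_coords(b)), integer(1))
  u_mat <- matrix(NA_real_, sum(N_k), K)
  frac_rej <- matrix(0, K, K)
  row0 <- c(0L, cumsum(N_k))
  for (k in seq_len(K)) {
    rows <- row0[k] + seq_len(N_k[k])
    for (i in seq_len(K)) {
      cm <- if (i == k) NULL else compose_maps(maps[[k]], maps[[i]])
      rv <- remapped_potential(cm, rpots[[i]], batches[[k]])
      u_mat[rows, i] <- rv$u
      frac_rej[k, i] <- rv$frac_rejected
    }
  }
  sol <- mbar_solve(u_mat, N_k)
  pairs <- list()
  for (i in seq_len(K - 1L)) {
    for (j in (i + 1L):K) {
      se <- sqrt(max(sol$covariance[i, i] + sol$covariance[j, j] -
                       2 * sol$covariance[i, j], 0))
      pairs[[paste0(i, "-", j)]] <-
        fe_estimate(sol$f[j] - sol$f[i], se, estimator = "MBAR",
                    split = split, n_used = sum(N_k))
    }
  }
  list(f = sol$f, covariance = sol$covariance, pairs = pairs,
       frac_rejected = frac_rej, residual = sol$residual)
}
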