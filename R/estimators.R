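# The six free-energy estimators and the targeted (remapped)
# machinery around them.
#
# Everything is built on the generalized work function
#   phi_i(r) = u_i(r) + ln q_i(r),
# where u_i is the (restricted) reduced potential of state i and q_i
# the normalized flow density.  The defining identities
# 1 = <q^{-1} p>_q and 1 = <p^{-1} q>_p give, with p = exp(f - u_i),
#   <exp(-phi)>_q = exp(-f)   and   <exp(phi)>_p = exp(f),
# so phi is the per-configuration quantity whose (exponential)
# averages yield the reduced free energy f = -ln Z_i; when the map is
# perfect (q_i = p_i), phi_i is constant and equals f_i, and every
# estimator below coincides.

#' Restricted reduced potential of a metastable state
#'
#' Enforces the state's integration limits: configurations assigned
#' to the target state keep their plain energy; all others receive a
#' large penalty (1e20 by convention) so their Boltzmann weight is
#' exactly zero in the estimation path.  Internally penalized rows
#' are treated as `+Inf` in all weighting arithmetic to avoid
#' overflow; [restricted_u()] reports the conventional `u + 1e20`.
#'
#' @param pot a [reduced_potential()] (the single global surface).
#' @param state target state label.
#' @param assigner a [cluster_assigner()]; `NULL` disables the
#'   restriction (plain global potential).
#' @param penalty reported penalty magnitude (default 1e20).
#' @return object of class `restricted_potential`.
#' @export
restricted_potential <- function(pot, state, assigner, penalty = 1e20) {
  stopifnot(is.null(assigner) || penalty > 0)
  structure(list(pot = pot, state = as.integer(state),
                 assigner = assigner, penalty = penalty),
            class = "restricted_potential")
}

# reduced energies with out-of-state rows as +Inf (weight-path form);
# out-of-domain rows (NA label) are penalized too
ru_eval <- function(rp, R) {
  R <- batch_coords(R)
  if (inherits(rp, "reduced_potential")) return(rp_eval(rp, R))
  u <- rp_eval(rp$pot, R)
  if (!is.null(rp$assigner)) {
    lab <- assign_cluster(rp$assigner, R)
    u[!(lab %in% rp$state)] <- Inf
  }
  u
}

#' Restricted potential values (reporting convention)
#'
#' @param rp a [restricted_potential()].
#' @param R matrix of configurations or a `sample_batch`.
#' @return plain `u(r)` for in-state rows, `u(r) + penalty`
#'   otherwise.
#' @export
restricted_u <- function(rp, R) {
  R <- batch_coords(R)
  u <- rp_eval(rp$pot, R)
  if (!is.null(rp$assigner)) {
    lab <- assign_cluster(rp$assigner, R)
    bad <- !(lab %in% rp$state)
    u[bad] <- u[bad] + rp$penalty
  }
  u
}

#' Generalized work function values
#'
#' `phi_i(r) = u_i(r) + ln q_i(r)` per configuration.  Rows where
#' either term is non-finite (model samples that left the state or
#' the domain) are `+Inf`/`-Inf` and are excluded, with their count
#' reported, by the downstream q-side averages; for in-state MD
#' samples all values are finite by construction.
#'
#' @param map the state's flow map (anything supporting
#'   [flow_log_q()]).
#' @param base a [base_uniform()].
#' @param rpot the state's [restricted_potential()] (or plain
#'   [reduced_potential()]).
#' @param batch configurations (`sample_batch` or matrix).
#' @return object of class `work_values`: `phi`, the origin tag, and
#'   bookkeeping counts.
#' @export
work_function <- function(map, base, rpot, batch) {
  R <- batch_coords(batch)
  stopifnot(nrow(R) >= 1)
  u <- if (inherits(rpot, "restricted_potential")) {
    ru_eval(rpot, R)
  } else {
    rp_eval(rpot, R)
  }
  lq <- if (inherits(batch, "sample_batch") && !is.null(batch$log_q)) {
    batch$log_q
  } else {
    flow_log_q(map, base, R)
  }
  phi <- u + lq
  phi[is.nan(phi)] <- Inf # u = +Inf with ln q = -Inf: zero weight
  structure(list(phi = phi, origin = batch_origin(batch),
                 n = length(phi), n_nonfinite = sum(!is.finite(phi))),
            class = "work_values")
}

.finite_phi <- function(phi_obj, min_n = 2L) {
  phi <- phi_obj$phi[is.finite(phi_obj$phi)]
  if (length(phi) < min_n) {
    stop("need at least ", min_n, " finite work-function values")
  }
  phi
}

#' Work-function averaging estimator (AVMD / AVBG)
#'
#' `f ~ mean(phi)`: exact only in the perfect-map limit, where the
#' work function is constant.  Labeled AVMD when the samples come
#' from the physical state (MD data), AVBG when they come from the
#' flow model (Boltzmann-generator data).
#'
#' @param phi a `work_values` object from [work_function()].
#' @param split `"T"`, `"V"` or `NA`.
#' @return a [fe_estimate()].
#' @export
estimate_AV <- function(phi, split = NA_character_) {
  v <- .finite_phi(phi)
  n <- length(v)
  fe_estimate(mean(v), stats::sd(v) / sqrt(n),
              estimator = if (phi$origin == "model") "AVBG" else "AVMD",
              split = split, n_used = n, n_dropped = phi$n - n)
}

#' Exponential-averaging estimators (EXPMD / EXPBG)
#'
#' One-directional reweighting: `EXPMD = ln <exp(phi)>_p` over
#' physical samples, `EXPBG = -ln <exp(-phi)>_q` over model samples;
#' both evaluated with log-sum-exp stabilization.  The standard
#' error is the first-order delta-method propagation of the weight
#' variance.
#'
#' @param phi a `work_values` object.
#' @param direction `"MD"` (p-samples) or `"BG"` (q-samples);
#'   defaults to the batch's origin tag.
#' @param split `"T"`, `"V"` or `NA`.
#' @return a [fe_estimate()].
#' @export
estimate_EXP <- function(phi, direction = NULL, split = NA_character_) {
  if (is.null(direction)) {
    direction <- if (phi$origin == "model") "BG" else "MD"
  }
  direction <- match.arg(direction, c("MD", "BG"))
  if (direction == "BG") {
    # -Inf weights (phi = +Inf) contribute zero but keep their count:
    # the model did generate them
    v <- phi$phi
    if (sum(is.finite(v)) < 2L) stop("no overlap: all weights underflow")
    n <- length(v)
    l1 <- logsumexp(-v) - log(n)
    l2 <- logsumexp(-2 * v) - log(n)
    value <- -l1
    relvar <- exp(l2 - 2 * l1) - 1
  } else {
    v <- .finite_phi(phi)
    n <- length(v)
    l1 <- logsumexp(v) - log(n)
    l2 <- logsumexp(2 * v) - log(n)
    value <- l1
    relvar <- exp(l2 - 2 * l1) - 1
  }
  fe_estimate(value, sqrt(max(relvar, 0) / n),
              estimator = paste0("EXP", direction), split = split,
              n_used = sum(is.finite(v)),
              n_dropped = sum(!is.finite(v)))
}

#' Bennett acceptance ratio estimator (two-directional)
#'
#' Solves the self-consistent mixture equation
#' `sum_n 1 / (N_p + N_q exp(phi_n - f)) = 1`, the sum running over
#' the pooled p- and q-samples, which is the empirical form of
#' `1 = <p_M^{-1} p>_{p_M}` with the mixture
#' `p_M = (N_p p + N_q q) / (N_p + N_q)`.  The left side is strictly
#' increasing in `f`, so the root is found by monotone bisection
#' (tolerance 1e-12), bracketed by the two exponential-averaging
#' estimates from the same data.  The analytic standard error is the
#' two-state case of the asymptotic multistate covariance.
#'
#' @param phi_p `work_values` evaluated on samples from the physical
#'   state p.
#' @param phi_q `work_values` evaluated on model (q) samples.
#' @param split `"T"`, `"V"` or `NA`.
#' @return a [fe_estimate()].
#' @export
estimate_BAR <- function(phi_p, phi_q, split = NA_character_) {
  wp <- .finite_phi(phi_p)
  if (sum(is.finite(phi_q$phi)) < 2L) stop("no overlap on the q side")
  wq <- phi_q$phi # +Inf allowed: zero-weight members of the q sample
  np <- length(wp)
  nq <- length(wq)
  pooled <- c(wp, wq)
  lM <- log(nq) - log(np)
  # residual(f) = (1/np) sum_n sigmoid(f - phi_n - log(nq/np)) - 1
  resid <- function(f) {
    sum(sigmoid(f - pooled - lM)) / np - 1
  }
  lo <- -logsumexp(-wq) + log(nq) # EXPBG from the q side
  hi <- logsumexp(wp) - log(np)   # EXPMD from the p side
  if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
  lo <- lo - 1e-6; hi <- hi + 1e-6
  while (resid(lo) > 0) lo <- lo - 1
  while (resid(hi) < 0) hi <- hi + 1
  for (it in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (resid(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  f <- (lo + hi) / 2
  if (!is.finite(f)) stop("no overlap: BAR root not bracketed")
  # asymptotic stderr from the K = 2 multistate covariance; the
  # per-sample energy matrix (0, phi) is gauge-equivalent to
  # (u_q, u_p)
  u_mat <- cbind(0, pooled)
  se <- tryCatch({
    V <- mbar_covariance(u_mat, c(nq, np), f = c(0, f))
    sqrt(max(V[1, 1] + V[2, 2] - 2 * V[1, 2], 0))
  }, error = function(e) NA_real_)
  fe_estimate(f, se, estimator = "BAR", split = split,
              n_used = np + sum(is.finite(wq)),
              n_dropped = phi_p$n - np + sum(!is.finite(wq)))
}

#' Remapped (effective) potential values
#'
#' Transports samples drawn in state k's coordinates into state i's
#' coordinates through the composed map and corrects by the
#' log-Jacobian: `u_{k->i}(r) = u_i(T_{k->i}(r)) - ln gamma(r)`.
#' Images that leave the domain or the target state's cluster get
#' `+Inf` (zero weight), with the affected fraction reported.
#'
#' @param map_composed a `composed_map` from [compose_maps()] (or any
#'   map supporting [map_apply()]); for k = i pass `NULL` to use the
#'   identity.
#' @param rpot_i the target state's [restricted_potential()].
#' @param batch samples drawn in state k's coordinates.
#' @return object of class `remapped_values`: `u` vector plus the
#'   out-of-state fraction.
#' @export
remapped_potential <- function(map_composed, rpot_i, batch) {
  R <- batch_coords(batch)
  if (is.null(map_composed)) {
    u <- ru_eval(rpot_i, R)
  } else {
    tr <- map_apply(map_composed, R)
    u <- ru_eval(rpot_i, tr$r) - tr$logdet
    u[is.nan(u)] <- Inf
  }
  structure(list(u = u, n = length(u),
                 frac_rejected = mean(!is.finite(u))),
            class = "remapped_values")
}

#' Configurational entropy decomposition
#'
#' Splits reduced free-energy differences into energetic and entropic
#' parts: `Delta f_ij = C_ij - Delta s_ij` with
#' `C_ij = <u_j>_{p_j} - <u_i>_{p_i}` estimated from the per-state
#' physical (MD-origin) data, so
#' `Delta s_ij = C_ij - Delta f_ij` (in units of k_B).  The energy
#' term is independent of the mapping quality; the entropy estimate
#' inherits the free-energy estimator's error, propagated in
#' quadrature with the energy-mean standard errors.
#'
#' @param delta_f K x K matrix of reduced free-energy differences
#'   with entry `(i, j) = f_j - f_i` (antisymmetric; the convention
#'   under which `Delta s_ij = s_j - s_i`).
#' @param delta_f_se K x K matrix of their standard errors (0 on the
#'   diagonal).
#' @param energies list of K numeric vectors: reduced energies of the
#'   MD samples of each state.
#' @return list with `delta_s` (K x K antisymmetric matrix of
#'   `s_j - s_i`), `stderr` (K x K) and the energy term `C`.
#' @export
entropy_decomposition <- function(delta_f, delta_f_se, energies) {
  K <- length(energies)
  stopifnot(all(dim(delta_f) == c(K, K)))
  if (any(vapply(energies, function(e) length(e) < 2L, logical(1)))) {
    stop("missing state energies")
  }
  ubar <- vapply(energies, mean, numeric(1))
  use <- vapply(energies, function(e) stats::sd(e) / sqrt(length(e)),
                numeric(1))
  C <- outer(ubar, ubar, function(ui, uj) uj - ui) # C_ij = <u_j> - <u_i>
  Cse2 <- outer(use^2, use^2, "+")
  ds <- C - delta_f
  se <- sqrt(Cse2 + delta_f_se^2)
  diag(se) <- 0
  list(delta_s = ds, stderr = se, C = C)
}
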