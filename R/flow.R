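# Invertible maps between the configuration space and a uniform base
# distribution on a box, with exact log-|det Jacobian| in both
# directions.
#
# Direction conventions (used consistently across the package):
#   * r -> z ("map_rz"): configuration space to base space.  For
#     spline-coupling flows this direction applies the analytic
#     rational-quadratic splines, so density evaluation (and hence
#     maximum-likelihood training) is cheap and differentiable.
#   * z -> r ("map_zr"): base to configuration space, used for
#     sampling the model; splines are inverted by the per-bin
#     quadratic solve.
#
# The normalized model density is
#   ln q(r) = -D ln L + log|det J_{r->z}|(r),   L = b - a,
# which is the remapped uniform base distribution: the flow transports
# the box measure onto configuration space and the Jacobian keeps q
# exactly normalized.

#' Uniform base distribution on a box
#'
#' @param D dimension.
#' @param a,b per-dimension interval endpoints (scalar; the box is
#'   `[a, b]^D`).
#' @return object of class `base_uniform` with the constant
#'   log-density `-D log(b - a)`.
#' @export
base_uniform <- function(D, a = 0, b = 1) {
  stopifnot(D >= 1, b > a)
  structure(list(D = as.integer(D), a = a, b = b,
                 log_density = -D * log(b - a)),
            class = "base_uniform")
}

#' Transform configurations to base coordinates
#'
#' Generic over map types. Returns `list(z, logdet)` where `logdet`
#' is the per-row `log|det J_{r->z}|`.
#'
#' @param map an invertible map object.
#' @param R numeric matrix of configurations (rows).
#' @export
map_rz <- function(map, R) UseMethod("map_rz")

#' Transform base coordinates to configurations
#'
#' Returns `list(r, logdet)` with the per-row `log|det J_{z->r}|`.
#'
#' @param map an invertible map object.
#' @param Z numeric matrix of base points (rows).
#' @export
map_zr <- function(map, Z) UseMethod("map_zr")

#' Dimension of a map
#' @param map an invertible map object.
#' @export
map_dim <- function(map) UseMethod("map_dim")

#' @export
map_dim.default <- function(map) map$D

as_config_matrix <- function(R, D) {
  if (is.null(dim(R))) R <- matrix(R, ncol = D)
  storage.mode(R) <- "double"
  stopifnot(ncol(R) == D)
  R
}

# ---- spline-coupling flow -----------------------------------------

# alternating half-masks: odd layers transform the second half of the
# coordinates conditioned on the first, even layers the reverse
coupling_masks <- function(D, n_layers) {
  first <- seq_len(ceiling(D / 2))
  second <- setdiff(seq_len(D), first)
  if (D == 1L) {
    first <- integer(0)
    second <- 1L
  }
  lapply(seq_len(n_layers), function(l) {
    if (D == 1L || l %% 2L == 1L) {
      list(idx_id = first, idx_tr = if (length(second)) second else first)
    } else {
      list(idx_id = second, idx_tr = first)
    }
  })
}

#' Create a spline-coupling flow map
#'
#' A sequence of coupling layers, each applying monotone
#' rational-quadratic splines to one half of the coordinates with
#' knots produced by a conditioner network reading the other half.
#' All parameters are initialized so that the map is exactly the
#' identity, i.e. the initial model density equals the uniform base.
#' For `D = 1` the conditioner degenerates to a learned unconditional
#' knot table per layer.
#'
#' @param D dimension of configuration space.
#' @param a,b box endpoints (base box equals the configuration
#'   domain).
#' @param n_layers number of coupling layers (default 4).
#' @param n_bins spline bins per transformed coordinate (default 16).
#' @param hidden conditioner hidden width (two tanh layers; default 64).
#' @param seed integer seed for conditioner initialization.
#' @return object of class `flow_map`.
#' @export
flow_create <- function(D, a = 0, b = 1, n_layers = 4L, n_bins = 16L,
                        hidden = 64L, seed = 1L) {
  stopifnot(D >= 1, n_layers >= 1, n_bins >= 2, b > a)
  masks <- coupling_masks(D, n_layers)
  d_raw <- 3L * n_bins - 1L
  params <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    d_in <- length(masks[[l]]$idx_id)
    d_out <- length(masks[[l]]$idx_tr) * d_raw
    params[[l]] <- mlp_init(d_in, hidden, d_out, seed = split_seed(seed, l))
  }
  structure(list(D = as.integer(D), a = a, b = b,
                 n_layers = as.integer(n_layers),
                 n_bins = as.integer(n_bins), hidden = as.integer(hidden),
                 masks = masks, params = params),
            class = "flow_map")
}

# conditioner input: identity-block coordinates rescaled to [-1, 1]
.cond_input <- function(map, X, l) {
  idx <- map$masks[[l]]$idx_id
  if (!length(idx)) return(matrix(0, nrow(X), 0L))
  2 * (X[, idx, drop = FALSE] - map$a) / (map$b - map$a) - 1
}

# knot tables for layer l given current coordinates (list: P, raw,
# mlp cache, flattened x ordering is column-major over idx_tr)
.layer_params <- function(map, X, l) {
  mf <- mlp_forward(map$params[[l]], .cond_input(map, X, l))
  ntr <- length(map$masks[[l]]$idx_tr)
  d_raw <- 3L * map$n_bins - 1L
  n <- nrow(X)
  raw <- matrix(0, n * ntr, d_raw)
  for (j in seq_len(ntr)) {
    raw[(j - 1L) * n + seq_len(n), ] <-
      mf$out[, (j - 1L) * d_raw + seq_len(d_raw), drop = FALSE]
  }
  list(P = rq_params(raw, map$n_bins, map$a, map$b), mlp = mf, ntr = ntr)
}

#' @export
map_rz.flow_map <- function(map, R) {
  X <- as_config_matrix(R, map$D)
  n <- nrow(X)
  ld <- numeric(n)
  for (l in seq_len(map$n_layers)) {
    lp <- .layer_params(map, X, l)
    tr <- map$masks[[l]]$idx_tr
    fw <- rq_forward(as.vector(X[, tr, drop = FALSE]), lp$P)
    X[, tr] <- matrix(fw$y, n)
    ld <- ld + rowSums(matrix(fw$logd, n))
  }
  list(z = X, logdet = ld)
}

#' @export
map_zr.flow_map <- function(map, Z) {
  X <- as_config_matrix(Z, map$D)
  n <- nrow(X)
  ld <- numeric(n)
  for (l in rev(seq_len(map$n_layers))) {
    lp <- .layer_params(map, X, l)
    tr <- map$masks[[l]]$idx_tr
    iv <- rq_inverse(as.vector(X[, tr, drop = FALSE]), lp$P)
    X[, tr] <- matrix(iv$x, n)
    ld <- ld + rowSums(matrix(iv$logd, n))
  }
  list(r = X, logdet = ld)
}

#' Normalized model log-density
#'
#' `ln q(r) = -D ln L + log|det J_{r->z}|(r)`. Rows outside the
#' domain box get `-Inf` (the model has zero mass there).
#'
#' @param map a map object supporting [map_rz()].
#' @param base a [base_uniform()] object.
#' @param R matrix of configurations.
#' @return numeric vector of log-densities.
#' @export
flow_log_q <- function(map, base, R) {
  R <- as_config_matrix(R, base$D)
  inside <- rowSums(R < base$a | R > base$b) == 0L
  out <- rep(-Inf, nrow(R))
  if (any(inside)) {
    tz <- map_rz(map, R[inside, , drop = FALSE])
    lq <- base$log_density + tz$logdet
    # zero mass where the inverse image leaves the base box
    lq[rowSums(tz$z < base$a - 1e-12 | tz$z > base$b + 1e-12) > 0L] <- -Inf
    out[inside] <- lq
  }
  out
}

#' Sample the flow model
#'
#' Draws base points uniformly in the box and pushes them through the
#' map (`z -> r`), returning configurations with their exact model
#' log-densities.
#'
#' @param map a map object supporting [map_zr()].
#' @param base a [base_uniform()] object.
#' @param n number of samples.
#' @param seed integer seed.
#' @return a `sample_batch` (see [sample_batch()]) with origin
#'   `"model"` and a `log_q` column.
#' @export
flow_sample <- function(map, base, n, seed) {
  stopifnot(n >= 1)
  set.seed(seed)
  Z <- matrix(stats::runif(n * base$D, base$a, base$b), n, base$D)
  tr <- map_zr(map, Z)
  sample_batch(tr$r, origin = "model",
               log_q = base$log_density - tr$logdet)
}

# ---- maximum-likelihood loss and gradient -------------------------

#' Negative mean log-likelihood of a batch under the flow
#'
#' The maximum-likelihood training loss: `-(1/N) sum_n ln q(r_n)`.
#' Any row with zero model density makes the loss `+Inf`.
#'
#' @param map a map object supporting [flow_log_q()].
#' @param base a [base_uniform()] object.
#' @param batch matrix of configurations or a `sample_batch`.
#' @return scalar loss.
#' @export
ml_loss <- function(map, base, batch) {
  R <- batch_coords(batch)
  stopifnot(nrow(R) >= 1)
  lq <- flow_log_q(map, base, R)
  if (any(!is.finite(lq))) {
    warning(sprintf("ml_loss: %d of %d rows have zero model density",
                    sum(!is.finite(lq)), length(lq)))
    return(Inf)
  }
  -mean(lq)
}

# loss + exact parameter gradient for one batch (training kernel)
flow_ml_grad <- function(map, base, X) {
  X <- as_config_matrix(X, map$D)
  if (any(X < map$a | X > map$b)) {
    stop("training batch contains configurations outside the domain box")
  }
  n <- nrow(X)
  L <- map$n_layers
  caches <- vector("list", L)
  ld <- numeric(n)
  for (l in seq_len(L)) {
    lp <- .layer_params(map, X, l)
    tr <- map$masks[[l]]$idx_tr
    fg <- rq_forward_grad(as.vector(X[, tr, drop = FALSE]), lp$P)
    caches[[l]] <- list(lp = lp, fg = fg)
    X[, tr] <- matrix(fg$y, n)
    ld <- ld + rowSums(matrix(fg$logd, n))
  }
  loss <- -base$log_density - mean(ld)
  # backward: d loss / d logd = -1/n elementwise
  G <- matrix(0, n, map$D)
  grads <- vector("list", L)
  d_raw <- 3L * map$n_bins - 1L
  for (l in rev(seq_len(L))) {
    tr <- map$masks[[l]]$idx_tr
    idx <- map$masks[[l]]$idx_id
    ntr <- length(tr)
    ca <- caches[[l]]
    bk <- rq_backward(ca$fg, ca$lp$P,
                      grad_y = as.vector(G[, tr, drop = FALSE]),
                      grad_logd = rep(-1 / n, n * ntr))
    G[, tr] <- matrix(bk$g_x, n)
    G_out <- matrix(0, n, ntr * d_raw)
    for (j in seq_len(ntr)) {
      G_out[, (j - 1L) * d_raw + seq_len(d_raw)] <-
        bk$g_raw[(j - 1L) * n + seq_len(n), , drop = FALSE]
    }
    mb <- mlp_backward(map$params[[l]], ca$lp$mlp$cache, G_out)
    grads[[l]] <- mb$grads
    if (length(idx)) {
      G[, idx] <- G[, idx, drop = FALSE] + mb$G_in * (2 / (map$b - map$a))
    }
  }
  list(loss = loss, grads = grads)
}

# ---- analytic reference maps --------------------------------------

#' Elementwise affine map
#'
#' `r = shift + scale * z`; an exact constant-Jacobian reference map.
#'
#' @param shift,scale numeric vectors of length D (scale > 0).
#' @param a,b base box endpoints.
#' @export
affine_map <- function(shift, scale, a = 0, b = 1) {
  stopifnot(length(shift) == length(scale), all(scale > 0), b > a)
  structure(list(D = length(shift), a = a, b = b,
                 shift = shift, scale = scale),
            class = "affine_map")
}

#' @export
map_rz.affine_map <- function(map, R) {
  R <- as_config_matrix(R, map$D)
  z <- sweep(sweep(R, 2L, map$shift, "-"), 2L, map$scale, "/")
  list(z = z, logdet = rep(-sum(log(map$scale)), nrow(R)))
}

#' @export
map_zr.affine_map <- function(map, Z) {
  Z <- as_config_matrix(Z, map$D)
  r <- sweep(sweep(Z, 2L, map$scale, "*"), 2L, map$shift, "+")
  list(r = r, logdet = rep(sum(log(map$scale)), nrow(Z)))
}

#' Exact Gaussian-to-uniform map
#'
#' Per dimension, `z = Phi((r - mean) / sd)` maps a Gaussian exactly
#' onto the uniform base box `[0, 1]`.  The perfect map for
#' independent-Gaussian states, used as an analytic reference in
#' estimator validation.
#'
#' @param mean,sd numeric vectors of length D (sd > 0).
#' @export
gaussian_cdf_map <- function(mean, sd) {
  stopifnot(length(mean) == length(sd), all(sd > 0))
  structure(list(D = length(mean), a = 0, b = 1, mean = mean, sd = sd),
            class = "gaussian_cdf_map")
}

#' @export
map_rz.gaussian_cdf_map <- function(map, R) {
  R <- as_config_matrix(R, map$D)
  z <- R; ld <- numeric(nrow(R))
  for (j in seq_len(map$D)) {
    z[, j] <- stats::pnorm(R[, j], map$mean[j], map$sd[j])
    ld <- ld + stats::dnorm(R[, j], map$mean[j], map$sd[j], log = TRUE)
  }
  list(z = z, logdet = ld)
}

#' @export
map_zr.gaussian_cdf_map <- function(map, Z) {
  Z <- as_config_matrix(Z, map$D)
  Z <- pmin(pmax(Z, 1e-15), 1 - 1e-15) # qnorm is infinite at the corners
  r <- Z; ld <- numeric(nrow(Z))
  for (j in seq_len(map$D)) {
    r[, j] <- stats::qnorm(Z[, j]) * map$sd[j] + map$mean[j]
    ld <- ld - stats::dnorm(r[, j], map$mean[j], map$sd[j], log = TRUE)
  }
  list(r = r, logdet = ld)
}

#' Identity map
#' @param D dimension.
#' @param a,b box endpoints.
#' @export
identity_map <- function(D, a = 0, b = 1) {
  affine_map(shift = rep(0, D), scale = rep(1, D), a = a, b = b)
}

# ---- composition --------------------------------------------------

#' Compose two state maps through the common base space
#'
#' Builds the transform from state `i` coordinates to state `j`
#' coordinates, `T_{i->j} = T_{z->r_j} o T_{r_i->z}`, with the
#' log-Jacobian accumulated over both stages.  Composed maps are the
#' building block of the remapped (effective) potentials used by
#' targeted MBAR: samples from every state are made comparable by
#' routing them through the shared base coordinate system.
#'
#' @param map_i map for the source state (its `r -> z` is applied).
#' @param map_j map for the target state (its `z -> r` is applied).
#' @return object of class `composed_map`; apply with [map_apply()].
#' @export
compose_maps <- function(map_i, map_j) {
  stopifnot(map_dim(map_i) == map_dim(map_j),
            isTRUE(all.equal(c(map_i$a, map_i$b), c(map_j$a, map_j$b))))
  structure(list(D = map_dim(map_i), a = map_i$a, b = map_i$b,
                 from = map_i, to = map_j),
            class = "composed_map")
}

#' Apply a composed map
#'
#' @param map a `composed_map`.
#' @param R matrix of source-state configurations.
#' @return `list(r, logdet)`: target-state configurations and the
#'   total log-Jacobian (sum of both stages).
#' @export
map_apply <- function(map, R) {
  t1 <- map_rz(map$from, R)
  t2 <- map_zr(map$to, t1$z)
  list(r = t2$r, logdet = t1$logdet + t2$logdet)
}

# ---- checkpoints --------------------------------------------------

#' Save a flow map to a JSON checkpoint
#'
#' Architecture metadata and all parameters, versioned; readable with
#' [load_flow()].
#'
#' @param map a `flow_map`.
#' @param path file path.
#' @export
save_flow <- function(map, path) {
  stopifnot(inherits(map, "flow_map"))
  obj <- list(format = "flowfe-checkpoint", version = 1L,
              D = map$D, a = map$a, b = map$b,
              n_layers = map$n_layers, n_bins = map$n_bins,
              hidden = map$hidden,
              params = lapply(map$params, function(net) {
                lapply(net, function(p) {
                  if (is.matrix(p)) {
                    list(dim = dim(p), data = as.vector(p))
                  } else {
                    list(dim = length(p), data = as.vector(p))
                  }
                })
              }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a flow map from a JSON checkpoint
#' @param path file path written by [save_flow()].
#' @export
load_flow <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "flowfe-checkpoint") ||
      !identical(as.integer(obj$version), 1L)) {
    stop("not a recognized flow checkpoint")
  }
  map <- flow_create(obj$D, obj$a, obj$b, obj$n_layers, obj$n_bins,
                     obj$hidden, seed = 1L)
  for (l in seq_len(map$n_layers)) {
    for (nm in names(map$params[[l]])) {
      rec <- obj$params[[l]][[nm]]
      p <- as.numeric(unlist(rec$data))
      dm <- as.integer(unlist(rec$dim))
      if (length(dm) == 2L) p <- matrix(p, dm[1], dm[2])
      map$params[[l]][[nm]] <- p
    }
  }
  map
}
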