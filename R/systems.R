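# Self-contained synthetic systems with known or quadrature-computable
# free energies: a 3D narrow-well toy potential whose six wells are
# grouped into three 2-modal metastable states, and Gaussian-mixture
# systems with closed-form free energies.  These play the role of the
# MD data sets: locally ergodic samples are drawn by cluster-restricted
# Metropolis Monte Carlo.

#' Reduced-potential evaluator
#'
#' Wraps a deterministic function `r -> u(r)` (energies in units of
#' k_B T) together with its dimension and bounded domain `[a, b]^D`.
#'
#' @param fn function taking a matrix of configurations (rows) and
#'   returning a numeric vector of reduced energies.
#' @param D dimension (>= 1).
#' @param a,b domain interval per dimension.
#' @return object of class `reduced_potential`.
#' @export
reduced_potential <- function(fn, D, a = 0, b = 1) {
  stopifnot(is.function(fn), D >= 1, b > a)
  structure(list(fn = fn, D = as.integer(D), a = a, b = b),
            class = "reduced_potential")
}

#' Evaluate a reduced potential on configurations
#' @param pot a `reduced_potential`.
#' @param R matrix of configurations (rows) or a `sample_batch`.
#' @return numeric vector of reduced energies.
#' @export
rp_eval <- function(pot, R) {
  R <- as_config_matrix(batch_coords(R), pot$D)
  pot$fn(R)
}

#' Deterministic cluster assignment
#'
#' A fixed, total rule mapping every in-domain configuration to
#' exactly one metastable-state label; fixed a priori, before any
#' estimation is run.  Out-of-domain configurations get the sentinel
#' label `NA`.
#'
#' @param fn function mapping a configuration matrix to integer
#'   labels.
#' @param n_states number of distinct labels.
#' @return object of class `cluster_assigner`.
#' @export
cluster_assigner <- function(fn, n_states) {
  structure(list(fn = fn, n_states = as.integer(n_states)),
            class = "cluster_assigner")
}

#' Assign configurations to metastable states
#' @param assigner a `cluster_assigner`.
#' @param R matrix of configurations or a `sample_batch`.
#' @return integer labels (NA for out-of-domain rows).
#' @export
assign_cluster <- function(assigner, R) {
  assigner$fn(as.matrix(batch_coords(R)))
}

# squared distances from rows of R to each center (n x n_wells)
.dist2_to_centers <- function(R, centers) {
  n <- nrow(R)
  K <- nrow(centers)
  d2 <- matrix(0, n, K)
  for (k in seq_len(K)) {
    d2[, k] <- rowSums(sweep(R, 2L, centers[k, ], "-")^2)
  }
  d2
}

#' Build the narrow-well toy system
#'
#' Six isotropic harmonic wells on a bounded cube, grouped into three
#' two-well (2-modal) metastable states.  The reduced potential is
#' the hard minimum over wells,
#' `u(r) = min_k (depth_k + stiffness_k/2 * |r - c_k|^2)`,
#' and the cluster rule is nearest well center (lowest index on ties)
#' mapped through the well grouping.  Ground truth for each state is
#' recomputed by quadrature, so the exact functional form matters
#' only through its structure: narrow, non-overlapping, multimodal
#' states.
#'
#' @param centers 6 x D matrix of well centers (D = 3 for the
#'   standard system).
#' @param stiffness positive vector of 6 spring constants (reduced
#'   units); the local Gaussian of well k has sd `1/sqrt(k_k)`.
#' @param depth vector of 6 well depths (reduced units).
#' @param group integer vector of 6 state labels; each label must
#'   appear exactly twice.
#' @param a,b domain cube `[a, b]^D`.
#' @return object of class `toy_system` with elements `pot`
#'   (a [reduced_potential()]) and `assigner` (a
#'   [cluster_assigner()]).
#' @export
build_toy_system <- function(centers, stiffness, depth, group,
                             a = 0, b = 1) {
  centers <- as.matrix(centers)
  if (nrow(centers) != 6L) {
    stop("toy system requires exactly 6 wells, got ", nrow(centers))
  }
  if (any(stiffness <= 0)) stop("well stiffness must be positive")
  stopifnot(length(stiffness) == 6L, length(depth) == 6L,
            length(group) == 6L)
  tab <- table(group)
  if (length(tab) != 3L || any(tab != 2L)) {
    stop("grouping must assign exactly 2 wells to each of 3 states")
  }
  sd_local <- 1 / sqrt(stiffness)
  dmat <- as.matrix(stats::dist(centers))
  sep <- outer(sd_local, sd_local, pmax) * 5
  diag(dmat) <- Inf
  if (any(dmat < sep)) {
    stop("well centers must be separated by >= 5 local standard deviations")
  }
  D <- ncol(centers)
  pot_fn <- function(R) {
    d2 <- .dist2_to_centers(R, centers)
    u <- d2[, 1L] * (stiffness[1L] / 2) + depth[1L]
    for (k in 2:6) u <- pmin(u, d2[, k] * (stiffness[k] / 2) + depth[k])
    u
  }
  assign_fn <- function(R) {
    d2 <- .dist2_to_centers(R, centers)
    nearest <- max.col(-d2, ties.method = "first")
    lab <- as.integer(group[nearest])
    out <- rowSums(R < a | R > b) > 0L
    lab[out] <- NA_integer_
    lab
  }
  structure(list(centers = centers, stiffness = stiffness, depth = depth,
                 group = as.integer(group), a = a, b = b, D = D,
                 pot = reduced_potential(pot_fn, D, a, b),
                 assigner = cluster_assigner(assign_fn, 3L)),
            class = "toy_system")
}

#' The default narrow-well study system
#'
#' The standard conditions used throughout the package's convergence
#' study: six wells of stiffness 200 (local sd ~0.071) at interior
#' positions of the unit cube with minimum pairwise center distance
#' 0.5, depths `(0, 1, 0.5, 0.5, 2, 0)` so the three states have
#' distinct free energies, grouped `(1,1,2,2,3,3)` with the two wells
#' of each state on opposite sides of the cube (strongly anharmonic,
#' 2-modal states).
#'
#' @return a `toy_system`.
#' @export
default_toy_system <- function() {
  centers <- rbind(c(0.25, 0.25, 0.25),
                   c(0.75, 0.75, 0.75),
                   c(0.25, 0.75, 0.25),
                   c(0.75, 0.25, 0.75),
                   c(0.25, 0.25, 0.75),
                   c(0.75, 0.75, 0.25))
  build_toy_system(centers,
                   stiffness = rep(200, 6),
                   depth = c(0, 1, 0.5, 0.5, 2, 0),
                   group = c(1L, 1L, 2L, 2L, 3L, 3L))
}

#' State free energy by grid quadrature
#'
#' Midpoint-rule evaluation of `f_i = -ln sum_g exp(-u(r_g)) dV` over
#' the grid points assigned to state `i`; the low-dimensional ground
#' truth facility.  Refuses dimensions above 3, where quadrature is
#' no longer a practical ground truth.
#'
#' @param pot a [reduced_potential()] on a bounded domain.
#' @param assigner a [cluster_assigner()]; `NULL` integrates the
#'   whole domain.
#' @param state integer state label (ignored when `assigner` is
#'   `NULL`).
#' @param grid_n grid resolution per dimension (>= 64 for production
#'   use; smaller values are permitted for quick checks).
#' @return scalar reduced free energy.
#' @export
quadrature_free_energy <- function(pot, assigner = NULL, state = NULL,
                                   grid_n = 128L) {
  if (pot$D > 3L) {
    stop("quadrature ground truth is restricted to D <= 3")
  }
  if (!is.finite(pot$a) || !is.finite(pot$b)) stop("domain must be bounded")
  g <- pot$a + (pot$b - pot$a) * (seq_len(grid_n) - 0.5) / grid_n
  dv <- ((pot$b - pot$a) / grid_n)^pot$D
  if (pot$D == 1L) {
    slices <- list(matrix(g, ncol = 1L))
  } else if (pot$D == 2L) {
    slices <- list(as.matrix(expand.grid(x1 = g, x2 = g)))
  } else {
    # chunk the grid over the last coordinate to bound memory
    plane <- as.matrix(expand.grid(x1 = g, x2 = g))
    slices <- lapply(g, function(z) cbind(plane, x3 = z))
  }
  lse_parts <- vapply(slices, function(S) {
    u <- rp_eval(pot, S)
    if (!is.null(assigner)) {
      keep <- assign_cluster(assigner, S) == state
      u <- u[keep %in% TRUE]
    }
    if (!length(u)) return(-Inf)
    logsumexp(-u)
  }, numeric(1))
  -(logsumexp(lse_parts) + log(dv))
}

#' Sample a metastable state by cluster-restricted Metropolis MC
#'
#' Draws locally ergodic samples from the Boltzmann distribution of
#' `pot` restricted to the region assigned to `state`.  `n`
#' independent walkers start at the state's first well center (toy
#' systems) or the supplied initial point and evolve by
#' Metropolis random walk; proposals whose cluster label differs
#' from the target state (or leave the domain) are rejected, which
#' enforces local ergodicity within the state.  For 2-modal toy
#' states a symmetric mode-hop move (translation by the inter-well
#' vector) lets walkers equilibrate between the state's two wells.
#'
#' @param system a `toy_system`, or a list with elements `pot`
#'   (reduced_potential) and `assigner` (cluster_assigner).
#' @param state target state label.
#' @param n number of samples (one per walker).
#' @param seed integer seed.
#' @param n_steps Metropolis steps per walker (default 400).
#' @param step proposal standard deviation; default `1.1 / sqrt(max
#'   stiffness)` for toy systems (tuned to ~40% acceptance), else
#'   5% of the domain width.
#' @param init optional initial configuration (must be assigned to
#'   `state`).
#' @param hop_prob probability of proposing a mode-hop move (toy
#'   systems with 2-well states; default 0.25).
#' @return a `sample_batch` with origin `"md"`, cached energies, and
#'   attribute `acceptance` (mean acceptance rate of local moves).
#' @export
sample_state <- function(system, state, n, seed, n_steps = 400L,
                         step = NULL, init = NULL, hop_prob = 0.25) {
  stopifnot(n >= 1)
  pot <- system$pot
  assigner <- system$assigner
  D <- pot$D
  hop <- NULL
  if (inherits(system, "toy_system")) {
    wells <- which(system$group == state)
    if (!length(wells)) stop("unknown state label ", state)
    if (is.null(init)) init <- system$centers[wells[1L], ]
    if (is.null(step)) step <- 1.1 / sqrt(max(system$stiffness[wells]))
    if (length(wells) == 2L) {
      hop <- system$centers[wells[2L], ] - system$centers[wells[1L], ]
    }
  } else {
    if (is.null(init)) stop("init required for non-toy systems")
    if (is.null(step)) step <- 0.05 * (pot$b - pot$a)
  }
  init <- as.numeric(init)
  if (!identical(as.integer(assign_cluster(assigner, matrix(init, 1L))),
                 as.integer(state))) {
    stop("initial configuration is not assigned to state ", state)
  }
  set.seed(seed)
  X <- matrix(init, n, D, byrow = TRUE)
  u <- rp_eval(pot, X)
  n_acc <- 0L
  n_loc <- 0L
  for (s in seq_len(n_steps)) {
    prop <- X + matrix(stats::rnorm(n * D, 0, step), n, D)
    is_hop <- FALSE
    if (!is.null(hop) && stats::runif(1) < hop_prob) {
      # symmetric translation between the state's two wells
      sgn <- sample(c(-1, 1), n, replace = TRUE)
      prop <- prop + sgn %o% hop
      is_hop <- TRUE
    }
    ok <- assign_cluster(assigner, prop) %in% state
    u_prop <- rep(Inf, n)
    if (any(ok)) u_prop[ok] <- rp_eval(pot, prop[ok, , drop = FALSE])
    acc <- log(stats::runif(n)) < (u - u_prop)
    X[acc, ] <- prop[acc, , drop = FALSE]
    u[acc] <- u_prop[acc]
    if (!is_hop) {
      n_acc <- n_acc + sum(acc)
      n_loc <- n_loc + n
    }
  }
  out <- sample_batch(X, origin = "md", state = state, energy = u)
  attr(out, "acceptance") <- n_acc / max(n_loc, 1L)
  attr(out, "seed") <- seed
  out
}

# ---- Gaussian mixture systems -------------------------------------

#' Gaussian-mixture system with closed-form free energies
#'
#' Each state's reduced potential is
#' `u_i(x) = -ln sum_k a_k N(x; mu_k, diag(sd_k^2))`, so the state's
#' configuration integral is `Z_i = sum_k a_k` and its free energy
#' `f_i = -ln sum_k a_k` is available in closed form, as is its
#' differential entropy for single-component states.  A synthetic
#' analytic surrogate for simulation-based ground truth.
#'
#' @param states list of states; each a list with `means` (m x D
#'   matrix), `sds` (m x D matrix of per-dimension standard
#'   deviations) and `weights` (m positive component weights, not
#'   necessarily normalized).
#' @param bound half-width of the bounded quadrature/sampling box
#'   around the component means (default 8 max sds).
#' @return object of class `gm_system`: per-state potentials
#'   (`pots`), exact free energies (`f_true`), and samplers.
#' @export
gaussian_mixture_system <- function(states, bound = NULL) {
  K <- length(states)
  stopifnot(K >= 1)
  D <- ncol(as.matrix(states[[1L]]$means))
  pots <- vector("list", K)
  f_true <- numeric(K)
  for (i in seq_len(K)) {
    st <- states[[i]]
    means <- as.matrix(st$means)
    sds <- as.matrix(st$sds)
    wts <- as.numeric(st$weights)
    stopifnot(all(wts > 0), all(sds > 0), nrow(means) == length(wts))
    lo <- min(means - 8 * sds)
    hi <- max(means + 8 * sds)
    if (!is.null(bound)) {
      lo <- min(lo, -bound)
      hi <- max(hi, bound)
    }
    f_true[i] <- -log(sum(wts))
    local({
      means <- means; sds <- sds; wts <- wts
      pots[[i]] <<- reduced_potential(function(R) {
        lp <- matrix(0, nrow(R), length(wts))
        for (k in seq_along(wts)) {
          lk <- log(wts[k])
          for (j in seq_len(ncol(R))) {
            lk <- lk + stats::dnorm(R[, j], means[k, j], sds[k, j], log = TRUE)
          }
          lp[, k] <- lk
        }
        -row_logsumexp(lp)
      }, D = D, a = lo, b = hi)
    })
  }
  structure(list(states = states, pots = pots, f_true = f_true,
                 D = D, K = K),
            class = "gm_system")
}

#' Draw exact samples from one state of a Gaussian-mixture system
#'
#' @param gm a `gm_system`.
#' @param state state index.
#' @param n number of samples.
#' @param seed integer seed.
#' @return a `sample_batch` with origin `"md"`.
#' @export
gm_sample <- function(gm, state, n, seed) {
  st <- gm$states[[state]]
  means <- as.matrix(st$means)
  sds <- as.matrix(st$sds)
  wts <- as.numeric(st$weights)
  set.seed(seed)
  comp <- sample.int(length(wts), n, replace = TRUE, prob = wts)
  X <- means[comp, , drop = FALSE] +
    matrix(stats::rnorm(n * gm$D), n) * sds[comp, , drop = FALSE]
  sample_batch(X, origin = "md", state = state,
               energy = rp_eval(gm$pots[[state]], X))
}
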