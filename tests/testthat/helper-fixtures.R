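# Shared fixtures: all built in code at test time.

# bare work-function value container (bypasses the map when the phi
# values themselves are the object under test)
wv <- function(phi, origin = "md") {
  structure(list(phi = phi, origin = origin, n = length(phi),
                 n_nonfinite = sum(!is.finite(phi))),
            class = "work_values")
}

# a flow with moderately perturbed parameters (representative of a
# partially trained model; large raw-parameter noise makes the
# splines pathologically sharp, which no trained model exhibits)
perturbed_flow <- function(D, seed, sd_b3 = 1, sd_W3 = 0.03, ...) {
  map <- flow_create(D, seed = seed, ...)
  set.seed(seed + 1000L)
  for (l in seq_len(map$n_layers)) {
    map$params[[l]]$b3 <- map$params[[l]]$b3 +
      stats::rnorm(length(map$params[[l]]$b3), 0, sd_b3)
    if (!is.null(map$params[[l]]$W3)) {
      map$params[[l]]$W3 <- map$params[[l]]$W3 +
        stats::rnorm(length(map$params[[l]]$W3), 0, sd_W3)
    }
  }
  map
}

# six-well system with k = 50 wells at cube corners (the widest wells
# that still satisfy the 5-sigma separation rule on the unit cube)
corner_toy_system <- function(stiffness = 50, depth = rep(0, 6)) {
  cc <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))[1:6, ]
  build_toy_system(cc, rep(stiffness, 6), depth, c(1, 1, 2, 2, 3, 3))
}

# 3-state 1D Gaussian system with closed-form f_i and s_i:
# u_i = (x - mu_i)^2 / (2 sd_i^2) + depth_i
# f_i = depth_i - log(sd_i * sqrt(2 pi)); s_i = 0.5 log(2 pi e sd_i^2)
gauss3 <- function(mu = c(-2, 0, 3), sd = c(0.5, 1, 2),
                   depth = c(0, 0.7, -0.3)) {
  pots <- lapply(1:3, function(i) {
    reduced_potential(function(R) {
      (R[, 1] - mu[i])^2 / (2 * sd[i]^2) + depth[i]
    }, D = 1, a = -20, b = 20)
  })
  list(mu = mu, sd = sd, depth = depth,
       pots = pots,
       maps = lapply(1:3, function(i) gaussian_cdf_map(mu[i], sd[i])),
       f = depth - 0.5 * log(2 * pi * sd^2),
       s = 0.5 * log(2 * pi * exp(1) * sd^2))
}
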