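# Synthetic systems: construction rules, quadrature ground truth,
# cluster assignment, cluster-restricted sampling.

test_that("toy-system construction enforces its preconditions", {
  cc <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))[1:6, ]
  expect_s3_class(corner_toy_system(), "toy_system")
  expect_error(build_toy_system(cc[1:5, ], rep(50, 5), rep(0, 5),
                                c(1, 1, 2, 2, 3)),
               "exactly 6 wells")
  expect_error(build_toy_system(cc, c(-1, rep(50, 5)), rep(0, 6),
                                c(1, 1, 2, 2, 3, 3)),
               "positive")
  expect_error(build_toy_system(cc, rep(50, 6), rep(0, 6),
                                c(1, 1, 1, 2, 2, 3)),
               "exactly 2 wells")
  # k = 4 wells have sd 0.5; corners are closer than 5 sd
  expect_error(build_toy_system(cc, rep(4, 6), rep(0, 6),
                                c(1, 1, 2, 2, 3, 3)),
               "separated")
})

test_that("quadrature reproduces the isolated-well Gaussian integral", {
  # single well, k = 50, depth 0, centered: f = -(3/2) ln(2 pi / 50)
  pot <- reduced_potential(function(R) {
    25 * rowSums((R - 0.5)^2)
  }, D = 3, a = -1, b = 2)
  f <- quadrature_free_energy(pot, grid_n = 128L)
  expect_equal(f, -1.5 * log(2 * pi / 50), tolerance = 1e-3)
})

test_that("quadrature of the flat potential on the unit cube is zero", {
  pot <- reduced_potential(function(R) rep(0, nrow(R)), D = 3)
  expect_equal(quadrature_free_energy(pot, grid_n = 64L), 0,
               tolerance = 1e-12)
  expect_error(quadrature_free_energy(
    reduced_potential(function(R) rep(0, nrow(R)), D = 4)), "D <= 3")
})

test_that("state free energies are stable under grid refinement and close cycles", {
  sys <- default_toy_system()
  f64 <- vapply(1:3, function(s) {
    quadrature_free_energy(sys$pot, sys$assigner, s, 64L)
  }, numeric(1))
  f128 <- vapply(1:3, function(s) {
    quadrature_free_energy(sys$pot, sys$assigner, s, 128L)
  }, numeric(1))
  expect_lt(max(abs(f128 - f64)), 1e-3)
  df <- outer(f128, f128, "-")
  expect_equal(df[1, 2] + df[2, 3] + df[3, 1], 0)
})

test_that("quadrature reproduces the Gaussian-mixture closed form", {
  gm <- gaussian_mixture_system(list(
    list(means = rbind(-1, 1.5), sds = rbind(0.3, 0.5),
         weights = c(0.8, 0.5))))
  expect_equal(gm$f_true[1], -log(1.3))
  f <- quadrature_free_energy(gm$pots[[1]], grid_n = 2048L)
  expect_equal(f, gm$f_true[1], tolerance = 1e-3)
})

test_that("cluster assignment is deterministic, total, and tie-broken by index", {
  sys <- default_toy_system()
  # well centers map to their own group
  expect_identical(assign_cluster(sys$assigner, sys$centers),
                   sys$group)
  # repeated calls identical
  R <- matrix(runif(300), 100, 3)
  expect_identical(assign_cluster(sys$assigner, R),
                   assign_cluster(sys$assigner, R))
  # out-of-domain gets the sentinel
  expect_identical(assign_cluster(sys$assigner, matrix(c(1.5, 0.5, 0.5), 1)),
                   NA_integer_)
  # equidistant point: lowest well index wins
  sys2 <- corner_toy_system()
  mid <- matrix(0.5, 1, 3)
  expect_identical(assign_cluster(sys2$assigner, mid), sys2$group[1])
})

test_that("restricted sampling never leaves the target state", {
  sys <- default_toy_system()
  for (s in 1:3) {
    b <- sample_state(sys, s, 500, seed = 100 + s)
    expect_identical(unique(assign_cluster(sys$assigner, b)), s)
  }
  # n = 1: one walker, still in state
  b1 <- sample_state(sys, 2, 1, seed = 1)
  expect_identical(nrow(b1$coords), 1L)
  expect_identical(assign_cluster(sys$assigner, b1), 2L)
  # initialization outside the state is rejected
  expect_error(sample_state(sys, 1, 10, seed = 1,
                            init = sys$centers[3, ]), "not assigned")
})

test_that("single-well moments match the analytic Gaussian", {
  # isolated wells (deep enough that the partner well is never
  # visited): state 3 wells have depths 2 and 0; condition on the
  # dominant well
  sys <- default_toy_system()
  b <- sample_state(sys, 3, 20000, seed = 7)
  d2 <- flowfe:::.dist2_to_centers(b$coords, sys$centers)
  w <- max.col(-d2)
  X <- b$coords[w == 6L, , drop = FALSE]
  sd_t <- 1 / sqrt(200)
  n <- nrow(X)
  expect_lt(max(abs(colMeans(X) - sys$centers[6, ])), 3 * sd_t / sqrt(n))
  # sd of sd estimate ~ sd/sqrt(2n)
  expect_lt(max(abs(apply(X, 2, sd) - sd_t)), 3 * sd_t / sqrt(2 * n))
  # two-well occupancy matches Boltzmann weights exp(-2)/(1+exp(-2))
  p6 <- 1 / (1 + exp(-2))
  expect_lt(abs(mean(w == 6L) - p6),
            3 * sqrt(p6 * (1 - p6) / length(w)) + 0.01)
})

test_that("sampling is reproducible and seeds decorrelate", {
  sys <- default_toy_system()
  b1 <- sample_state(sys, 1, 50, seed = 11)
  b2 <- sample_state(sys, 1, 50, seed = 11)
  b3 <- sample_state(sys, 1, 50, seed = 12)
  expect_identical(b1$coords, b2$coords)
  expect_false(identical(b1$coords, b3$coords))
})

test_that("sample and system files round-trip", {
  sys <- default_toy_system()
  b <- sample_state(sys, 2, 20, seed = 3)
  p <- tempfile(fileext = ".csv")
  write_samples(b, p, settings = list(n_steps = 400))
  b2 <- read_samples(p)
  expect_equal(b2$coords, b$coords, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(b2$state, 2L)
  ps <- tempfile(fileext = ".json")
  write_system(sys, ps)
  sys2 <- read_system(ps)
  expect_equal(sys2$centers, sys$centers, ignore_attr = TRUE)
  expect_identical(sys2$group, sys$group)
  u <- runif(30)
  R <- matrix(u, 10, 3)
  expect_equal(rp_eval(sys2$pot, R), rp_eval(sys$pot, R))
  unlink(c(p, paste0(p, ".json"), ps))
})
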