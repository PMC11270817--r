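# Work functions, AV/EXP/BAR estimators, restricted and remapped
# potentials, entropy decomposition, diagnostics.

test_that("work function is constant on a flat well under a perfect map", {
  # target: uniform on [0.2, 0.8]^2 with u = 1.3 inside; the affine
  # map transports the base box exactly onto it, so
  # phi = u + ln(1/V) = f everywhere
  V <- 0.6^2
  f_true <- 1.3 + log(1 / V)
  map <- affine_map(shift = c(0.2, 0.2), scale = c(0.6, 0.6))
  base <- base_uniform(2)
  pot <- reduced_potential(function(R) rep(1.3, nrow(R)), D = 2)
  set.seed(21)
  R <- matrix(runif(400, 0.2, 0.8), 200, 2)
  phi <- work_function(map, base, pot, R)
  expect_equal(phi$phi, rep(f_true, 200), tolerance = 1e-12)
})

test_that("with a perfect map all five absolute estimators equal f exactly", {
  V <- 0.6^2
  f_true <- 1.3 + log(1 / V)
  map <- affine_map(shift = c(0.2, 0.2), scale = c(0.6, 0.6))
  base <- base_uniform(2)
  pot <- reduced_potential(function(R) rep(1.3, nrow(R)), D = 2)
  set.seed(22)
  Rp <- matrix(runif(400, 0.2, 0.8), 200, 2) # p-samples
  ms <- flow_sample(map, base, 200, seed = 23) # q-samples
  phi_p <- work_function(map, base, pot, Rp)
  phi_q <- work_function(map, base, pot, ms)
  for (e in list(estimate_AV(phi_p), estimate_AV(phi_q),
                 estimate_EXP(phi_p, "MD"), estimate_EXP(phi_q, "BG"),
                 estimate_BAR(phi_p, phi_q))) {
    expect_equal(e$value, f_true, tolerance = 1e-10)
    expect_lt(e$stderr, 1e-7)
  }
  expect_identical(estimate_AV(phi_p)$estimator, "AVMD")
  expect_identical(estimate_AV(phi_q)$estimator, "AVBG")
})

test_that("constant work values give the constant under every estimator", {
  cp <- wv(rep(2.5, 50))
  cq <- wv(rep(2.5, 80), origin = "model")
  expect_equal(estimate_AV(cp)$value, 2.5)
  expect_equal(estimate_AV(cp)$stderr, 0)
  expect_equal(estimate_EXP(cp, "MD")$value, 2.5)
  expect_equal(estimate_EXP(cq, "BG")$value, 2.5)
  expect_equal(estimate_BAR(cp, cq)$value, 2.5, tolerance = 1e-10)
  expect_error(estimate_AV(wv(rep(Inf, 5))), "finite")
})

test_that("AV estimators are offset from f by the quadrature KL terms", {
  # p = N(0.5, 0.05) (plus depth), q = N(0.5, 0.08): AVMD = f - KL(p||q),
  # AVBG = f + KL(q||p), both computable by quadrature
  sd_p <- 0.05
  sd_q <- 0.08
  f_true <- 0.4 - 0.5 * log(2 * pi * sd_p^2)
  pot <- reduced_potential(function(R) {
    (R[, 1] - 0.5)^2 / (2 * sd_p^2) + 0.4
  }, D = 1)
  map <- gaussian_cdf_map(0.5, sd_q)
  base <- base_uniform(1)
  g <- (seq_len(20000) - 0.5) / 20000
  lp <- dnorm(g, 0.5, sd_p, log = TRUE)
  lq <- dnorm(g, 0.5, sd_q, log = TRUE)
  kl_pq <- sum(exp(lp) * (lp - lq)) / 20000
  kl_qp <- sum(exp(lq) * (lq - lp)) / 20000
  set.seed(31)
  n <- 40000
  Rp <- matrix(rnorm(n, 0.5, sd_p))
  phi_p <- work_function(map, base, pot, Rp)
  av_md <- estimate_AV(phi_p)
  expect_equal(av_md$value, f_true - kl_pq, tolerance = 3 * av_md$stderr)
  ms <- flow_sample(map, base, n, seed = 32)
  phi_q <- work_function(map, base, pot, ms)
  av_bg <- estimate_AV(phi_q)
  expect_equal(av_bg$value, f_true + kl_qp, tolerance = 3 * av_bg$stderr)
  # and the exponential averages remain consistent estimators of f
  ex_md <- estimate_EXP(phi_p, "MD")
  ex_bg <- estimate_EXP(phi_q, "BG")
  expect_equal(ex_md$value, f_true, tolerance = 4 * ex_md$stderr)
  expect_equal(ex_bg$value, f_true, tolerance = 4 * ex_bg$stderr)
})

test_that("EXPBG under a too-narrow model is biased, shrinking under brute force", {
  # q = N(0.5, 0.02) much narrower than p = N(0.5, 0.06): the model
  # under-covers the target's tails, where the importance weights
  # exp(-phi) are largest.  A finite sample therefore underestimates
  # the partition function and the free-energy estimate sits above f
  # (by Jensen, -ln of an underestimated mean).  A brute-force run of
  # the same estimator at N = 2e6 reproduces the bias direction with
  # much smaller magnitude.
  sd_p <- 0.06
  f_true <- -0.5 * log(2 * pi * sd_p^2)
  pot <- reduced_potential(function(R) {
    (R[, 1] - 0.5)^2 / (2 * sd_p^2)
  }, D = 1)
  map <- gaussian_cdf_map(0.5, 0.02)
  base <- base_uniform(1)
  n_small <- 200
  reps <- 50
  set.seed(41)
  ests <- vapply(seq_len(reps), function(r) {
    ms <- flow_sample(map, base, n_small, seed = 400 + r)
    estimate_EXP(work_function(map, base, pot, ms), "BG")$value
  }, numeric(1))
  expect_gt(mean(ests), f_true) # biased high at small N
  # brute force: same sign of bias, far closer to the truth
  big <- flow_sample(map, base, 2e6, seed = 999)
  e_big <- estimate_EXP(work_function(map, base, pot, big), "BG")
  expect_gt(e_big$value, f_true)
  expect_lt(e_big$value - f_true, (mean(ests) - f_true) / 3)
})

test_that("BAR is invariant to common scaling of the sample counts", {
  set.seed(51)
  phi_p <- wv(rnorm(300, 0.5, 0.8))
  phi_q <- wv(rnorm(200, -0.2, 0.8), origin = "model")
  b1 <- estimate_BAR(phi_p, phi_q)
  # triple both sides (repeat the samples): same mixture weights
  b3 <- estimate_BAR(wv(rep(phi_p$phi, 3)),
                     wv(rep(phi_q$phi, 3), origin = "model"))
  expect_equal(b3$value, b1$value, tolerance = 1e-9)
})

test_that("BAR lies between the two exponential-averaging estimates", {
  set.seed(52)
  for (r in 1:100) {
    np <- sample(50:300, 1)
    nq <- sample(50:300, 1)
    mu <- rnorm(1)
    phi_p <- wv(rnorm(np, mu + abs(rnorm(1)), runif(1, 0.3, 2)))
    phi_q <- wv(rnorm(nq, mu - abs(rnorm(1)), runif(1, 0.3, 2)),
                origin = "model")
    lo <- estimate_EXP(phi_q, "BG")$value
    hi <- estimate_EXP(phi_p, "MD")$value
    bar <- estimate_BAR(phi_p, phi_q)$value
    expect_gte(bar, min(lo, hi) - 1e-9)
    expect_lte(bar, max(lo, hi) + 1e-9)
  }
})

test_that("restricted potentials penalize out-of-state configurations", {
  sys <- default_toy_system()
  rp <- restricted_potential(sys$pot, 1L, sys$assigner)
  r_in <- matrix(sys$centers[1, ], 1)
  r_out <- matrix(sys$centers[3, ], 1)
  expect_equal(restricted_u(rp, r_in), rp_eval(sys$pot, r_in))
  expect_equal(restricted_u(rp, r_out), rp_eval(sys$pot, r_out) + 1e20)
  # weight path: exactly zero weight, i.e. +Inf reduced energy
  expect_identical(flowfe:::ru_eval(rp, r_out), Inf)
})

test_that("remapped potentials reduce to u_i for k = i and shift by ln(V'/V) for affine maps", {
  sys <- default_toy_system()
  rp <- restricted_potential(sys$pot, 1L, sys$assigner)
  b <- sample_state(sys, 1, 100, seed = 61)
  rv <- remapped_potential(NULL, rp, b)
  expect_equal(rv$u, flowfe:::ru_eval(rp, b))
  # flat potential, pure volume change V -> V': u shifts by -ln gamma
  pot <- reduced_potential(function(R) rep(0, nrow(R)), D = 2)
  m_i <- affine_map(shift = c(0, 0), scale = c(0.5, 0.5)) # V = 0.25
  m_j <- affine_map(shift = c(0, 0), scale = c(0.8, 0.5)) # V' = 0.40
  R <- matrix(runif(100, 0, 0.5), 50, 2)
  rv2 <- remapped_potential(compose_maps(m_i, m_j), pot, R)
  expect_equal(rv2$u, rep(-log(0.40 / 0.25), 50), tolerance = 1e-10)
})

test_that("remapped Boltzmann weight integrates to Z_i from any source state", {
  # 1D Gaussians with perfect maps: quadrature of exp(-u_{k->i}) over
  # source coordinates equals Z_i regardless of k
  gs <- gauss3()
  Zi <- exp(-gs$f)
  g <- seq(-12, 12, length.out = 40001)
  dg <- g[2] - g[1]
  for (k in 1:3) {
    for (i in 1:3) {
      cm <- if (i == k) NULL else compose_maps(gs$maps[[k]], gs$maps[[i]])
      rv <- remapped_potential(cm, gs$pots[[i]], matrix(g))
      expect_equal(sum(exp(-rv$u)) * dg, Zi[i], tolerance = 1e-3)
    }
  }
})

test_that("entropy decomposition is antisymmetric and exact for Gaussians", {
  gs <- gauss3()
  set.seed(71)
  N <- 50000
  en <- lapply(1:3, function(i) {
    x <- rnorm(N, gs$mu[i], gs$sd[i])
    rp_eval(gs$pots[[i]], matrix(x))
  })
  df <- outer(gs$f, gs$f, function(a, b) b - a) # exact delta f
  dfse <- matrix(0, 3, 3)
  ed <- entropy_decomposition(df, dfse, en)
  expect_equal(diag(ed$delta_s), rep(0, 3))
  expect_equal(ed$delta_s, -t(ed$delta_s))
  ds_true <- outer(gs$s, gs$s, function(a, b) b - a)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(ed$delta_s[i, j], ds_true[i, j],
                 tolerance = 3 * ed$stderr[i, j])
  }
  # 1D Gaussians with stiffness k1, k2: delta s = 0.5 ln(k1 / k2)
  expect_equal(ds_true[1, 2], 0.5 * log((1 / 0.5^2) / (1 / 1^2)))
  expect_error(entropy_decomposition(df, dfse, en[1:2]), "dim|missing")
})

test_that("estimators converge to each other as the map approaches perfection", {
  # q = N(0.5, sd_p * (1 + eps)): as eps -> 0, var(phi) -> 0 and
  # AV, EXP and BAR collapse onto each other
  sd_p <- 0.05
  pot <- reduced_potential(function(R) {
    (R[, 1] - 0.5)^2 / (2 * sd_p^2)
  }, D = 1)
  base <- base_uniform(1)
  set.seed(81)
  Rp <- matrix(rnorm(5000, 0.5, sd_p))
  gaps <- vapply(c(0.5, 0.15, 0.05), function(eps) {
    map <- gaussian_cdf_map(0.5, sd_p * (1 + eps))
    phi_p <- work_function(map, base, pot, Rp)
    ms <- flow_sample(map, base, 5000, seed = round(1000 * eps))
    phi_q <- work_function(map, base, pot, ms)
    av <- estimate_AV(phi_p)$value
    ex <- estimate_EXP(phi_p, "MD")$value
    bar <- estimate_BAR(phi_p, phi_q)$value
    max(abs(av - ex), abs(ex - bar))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 0.01)
})

test_that("overfit diagnostics report argmax, growth flags and gaps", {
  mk <- function(batch, est, split, value, stderr, target = "1") {
    data.frame(batch = batch, target = target, estimator = est,
               split = split, value = value, stderr = stderr)
  }
  batches <- seq(50, 500, by = 50)
  tr <- rbind(
    mk(batches, "AVMD", "V", c(1, 2, 3, 4, 5, 4.5, 4, 3, 2, 1), 0.1),
    mk(batches, "AVMD", "T", seq(1, 10), 0.1),
    mk(batches, "BAR", "V", rep(5, 10), seq(0.1, 1.0, 0.1)),
    mk(batches, "MBAR", "V", rep(5, 10), rep(0.2, 10), target = "1-2"))
  d <- overfit_diagnostics(tr)
  expect_equal(d$avmdv_argmax$batch, 250)
  g <- d$stderr_growth
  expect_true(g$flag[g$estimator == "BAR"])
  expect_false(g$flag[g$estimator == "MBAR"])
  gap <- d$gap_series[d$gap_series$estimator == "AVMD", ]
  expect_equal(gap$gap, seq(1, 10) - c(1, 2, 3, 4, 5, 4.5, 4, 3, 2, 1))
  expect_error(overfit_diagnostics(tr[tr$batch == 50, ]), "2 evaluation")
})
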