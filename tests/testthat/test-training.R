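# Maximum-likelihood training: loss semantics, batch schedule,
# determinism, swap-and-reset, sanity fraction.

test_that("ml_loss is 0 for the identity flow on in-box data and D ln L for affine", {
  base <- base_uniform(2)
  X <- matrix(runif(200), 100, 2)
  expect_equal(ml_loss(flow_create(2, seed = 1), base, X), 0,
               tolerance = 1e-12)
  L <- 0.5
  map <- affine_map(shift = c(0.2, 0.2), scale = c(L, L))
  Xin <- matrix(runif(200, 0.2, 0.7), 100, 2)
  expect_equal(ml_loss(map, base, Xin), 2 * log(L), tolerance = 1e-12)
  # zero-density rows are reported, not dropped
  Xout <- rbind(Xin, c(0.9, 0.9))
  expect_warning(l <- ml_loss(map, base, Xout), "zero model density")
  expect_identical(l, Inf)
})

test_that("training loss matches the sample cross-entropy of a fitted Gaussian", {
  # for q close to p = N(0.5, 0.06) the loss approaches H(p)
  set.seed(101)
  x <- rnorm(6000, 0.5, 0.06)
  x <- matrix(x[x > 0 & x < 1][1:4000])
  cfg <- train_config(total_batches = 400, eval_stride = 400, seed = 2,
                      batch_size = 1000)
  res <- train_state_model(x[1:2000, , drop = FALSE],
                           x[2001:4000, , drop = FALSE], NULL, cfg,
                           hidden = 16L)
  h_true <- 0.5 * log(2 * pi * exp(1) * 0.06^2)
  final <- res$trace$value[res$trace$batch == 400 & res$trace$split == "T"]
  expect_lt(abs(final - h_true), 0.25)
})

test_that("the evaluation schedule produces the expected number of events", {
  set.seed(102)
  x <- matrix(runif(400), ncol = 1)
  cfg <- train_config(total_batches = 50, eval_stride = 50, seed = 3)
  res <- train_state_model(x[1:200, , drop = FALSE],
                           x[201:400, , drop = FALSE], NULL, cfg,
                           n_layers = 2L, n_bins = 4L)
  expect_identical(unique(res$trace$batch), 50L)
  expect_error(train_config(total_batches = 40, eval_stride = 50),
               "stride exceeds")
})

test_that("training is deterministic given the seed", {
  set.seed(103)
  x <- matrix(runif(600, 0.2, 0.8), ncol = 2)
  cfg <- train_config(total_batches = 30, eval_stride = 30, seed = 11,
                      batch_size = 150)
  r1 <- train_state_model(x[1:150, ], x[151:300, ], NULL, cfg,
                          n_layers = 2L, n_bins = 8L, hidden = 16L)
  r2 <- train_state_model(x[1:150, ], x[151:300, ], NULL, cfg,
                          n_layers = 2L, n_bins = 8L, hidden = 16L)
  expect_identical(r1$map$params, r2$map$params)
  expect_identical(r1$trace, r2$trace)
})

test_that("epoch sampling is without replacement", {
  cfg <- train_config(total_batches = 10, eval_stride = 10, seed = 4,
                      batch_size = 64)
  tr <- flowfe:::trainer_create(matrix(runif(256), 256, 1), cfg, 1,
                                n_layers = 2L, n_bins = 4L, hidden = 8L)
  seen <- integer(0)
  for (i in 1:4) { # one full epoch = 4 batches of 64 over 256 rows
    nb <- flowfe:::trainer_next_batch(tr)
    tr <- nb$tr
    idx <- match(nb$X[, 1], tr$data[, 1])
    seen <- c(seen, idx)
  }
  expect_identical(sort(seen), 1:256)
})

test_that("swap-and-reset restores the initial parameters and exchanges splits", {
  set.seed(104)
  x <- rnorm(2000, 0.5, 0.06)
  x <- matrix(x[x > 0 & x < 1][1:1200])
  losses <- list()
  cfg <- train_config(total_batches = 120, eval_stride = 30, seed = 5,
                      batch_size = 600, swap_at = 60)
  hook <- function(ev) losses[[length(losses) + 1L]] <<- ev
  res <- train_state_model(x[1:600, , drop = FALSE],
                           x[601:1200, , drop = FALSE], NULL, cfg,
                           hidden = 16L, hook = hook)
  l <- vapply(losses, `[[`, numeric(1), "loss_train")
  # loss drops over the first half, is reset above it right after the
  # swap, and drops again
  expect_lt(l[2], l[1])
  expect_gt(l[3], l[2]) # reset visible at the first post-swap event
  expect_lt(l[4], l[3])
})

test_that("energy sanity fraction matches the uniform measure of the sane region", {
  sys <- default_toy_system()
  # all samples at well minima
  expect_equal(energy_sanity_fraction(sys$centers, sys$pot, u_min = 0), 1)
  expect_error(energy_sanity_fraction(matrix(0, 0, 3), sys$pot), "empty")
  # untrained (identity) model: uniform samples; compare against the
  # quadrature measure of {u - u_min < 10}
  thr <- 10
  g <- (seq_len(96) - 0.5) / 96
  gr <- as.matrix(expand.grid(g, g, g))
  u <- rp_eval(sys$pot, gr)
  frac_quad <- mean(u - min(sys$depth) < thr)
  ms <- flow_sample(flow_create(3, seed = 6), base_uniform(3), 20000,
                    seed = 7)
  frac_mc <- energy_sanity_fraction(ms, sys$pot, threshold = thr,
                                    u_min = min(sys$depth))
  se <- sqrt(frac_quad * (1 - frac_quad) / 20000)
  expect_lt(abs(frac_mc - frac_quad), 4 * se + 1e-3)
})

test_that("training aborts with a diagnostic on divergent loss", {
  # data outside the model's support (out of the box) makes the loss
  # infinite at the first batch
  x <- matrix(c(runif(50), 1.5), ncol = 1)
  cfg <- train_config(total_batches = 5, eval_stride = 5, seed = 8,
                      batch_size = 51)
  expect_error(
    suppressWarnings(train_state_model(x, x, NULL, cfg, n_layers = 2L,
                                       n_bins = 4L)),
    "diverged|outside")
})
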