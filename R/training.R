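# Maximum-likelihood training of one flow per metastable state, with
# the split/swap/stride evaluation protocol used in the package's
# convergence studies: a 50:50 train/validation split, evaluation of
# all estimators every fixed number of batches, and an optional
# mid-training event at which the two splits are swapped and the
# trainable parameters are reset to their initial values (so the
# post-swap run repeats the protocol with the roles of the two data
# halves exchanged).

#' Training configuration
#'
#' @param total_batches total number of training batches.
#' @param learning_rate Adam learning rate (default 0.001; all other
#'   Adam constants at their usual defaults).
#' @param batch_size training examples per batch, drawn without
#'   replacement within each epoch (default 1000).
#' @param eval_stride evaluate every this many batches, the first
#'   evaluation after `eval_stride` batches (default 50).
#' @param split_frac fraction of the data assigned to the training
#'   split (default 0.5).
#' @param swap_at batch index at which the train/validation splits
#'   are swapped and parameters reset to their initial values;
#'   `NULL` disables swapping.
#' @param seed integer seed controlling initialization, shuffling and
#'   model-sample draws.
#' @return object of class `train_config`.
#' @export
train_config <- function(total_batches, learning_rate = 1e-3,
                         batch_size = 1000L, eval_stride = 50L,
                         split_frac = 0.5, swap_at = NULL, seed = 1L) {
  stopifnot(total_batches >= 1, learning_rate > 0, batch_size >= 1,
            eval_stride >= 1, split_frac > 0, split_frac < 1)
  if (eval_stride > total_batches) {
    stop("evaluation stride exceeds the total number of batches")
  }
  structure(list(total_batches = as.integer(total_batches),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 eval_stride = as.integer(eval_stride),
                 split_frac = split_frac,
                 swap_at = if (is.null(swap_at)) NULL else as.integer(swap_at),
                 seed = as.integer(seed)),
            class = "train_config")
}

# internal single-state trainer: owns the flow, the optimizer state
# and the epoch permutation (without-replacement batch sampling;
# partial final batches are dropped)
trainer_create <- function(train_coords, config, D, a = 0, b = 1,
                           n_layers = 4L, n_bins = 16L, hidden = 64L) {
  map <- flow_create(D, a, b, n_layers, n_bins, hidden,
                     seed = split_seed(config$seed, 1L))
  list(map = map, base = base_uniform(D, a, b),
       init_params = map$params,
       adam = adam_init(map$params),
       config = config,
       data = as_config_matrix(train_coords, D),
       perm = integer(0), cursor = 0L, epoch = 0L, batch = 0L)
}

# next without-replacement batch (reshuffles at epoch boundaries)
trainer_next_batch <- function(tr) {
  n <- nrow(tr$data)
  bs <- min(tr$config$batch_size, n)
  if (tr$cursor + bs > length(tr$perm)) {
    tr$epoch <- tr$epoch + 1L
    set.seed(split_seed(tr$config$seed, 1000L + tr$epoch))
    tr$perm <- sample.int(n)
    tr$cursor <- 0L
  }
  idx <- tr$perm[tr$cursor + seq_len(bs)]
  tr$cursor <- tr$cursor + bs
  list(tr = tr, X = tr$data[idx, , drop = FALSE])
}

trainer_step <- function(tr) {
  nb <- trainer_next_batch(tr)
  tr <- nb$tr
  fg <- flow_ml_grad(tr$map, tr$base, nb$X)
  if (!is.finite(fg$loss)) {
    stop("training diverged: non-finite loss at batch ", tr$batch + 1L)
  }
  up <- adam_step(tr$map$params, fg$grads, tr$adam,
                  lr = tr$config$learning_rate)
  tr$map$params <- up$params
  tr$adam <- up$state
  tr$batch <- tr$batch + 1L
  tr$last_loss <- fg$loss
  tr
}

# swap-and-reset: exchange the two data splits and restore Theta (and
# the optimizer) to their initial state
trainer_swap <- function(tr, new_data) {
  tr$data <- as_config_matrix(new_data, tr$map$D)
  tr$map$params <- tr$init_params
  tr$adam <- adam_init(tr$init_params)
  tr$perm <- integer(0)
  tr$cursor <- 0L
  tr$epoch <- 10000L * (tr$epoch %/% 10000L + 1L) # fresh shuffle stream
  tr
}

#' Fraction of model samples with sane energies
#'
#' The fraction of model-generated configurations whose reduced
#' energy lies within `threshold` (default 100 k_B T) of the
#' potential's minimum; a cheap indicator that the model places its
#' mass in physically reasonable regions during training.
#'
#' @param batch model samples (`sample_batch` or matrix).
#' @param pot a [reduced_potential()].
#' @param threshold energy window above the minimum, in k_B T
#'   (default 100; must be positive).
#' @param u_min reference minimum energy; defaults to the minimum of
#'   the evaluated batch energies (exact when the batch touches the
#'   well bottoms; pass the known minimum for strictness).
#' @return fraction in `[0, 1]`.
#' @export
energy_sanity_fraction <- function(batch, pot, threshold = 100,
                                   u_min = NULL) {
  stopifnot(threshold > 0)
  R <- batch_coords(batch)
  if (nrow(R) == 0L) stop("empty batch")
  u <- rp_eval(pot, R)
  if (is.null(u_min)) u_min <- min(u)
  mean(u - u_min < threshold)
}

# per-event single-state estimator sweep: AVMD/EXPMD on each data
# split, AVBG/EXPBG on fresh model samples, BAR against each split
evaluate_state_estimators <- function(map, base, rpot, train, val,
                                      n_model = 1000L, seed = 1L,
                                      pot = NULL) {
  ms <- flow_sample(map, base, n_model, seed = seed)
  phi_q <- work_function(map, base, rpot, ms)
  phi_t <- work_function(map, base, rpot, train)
  phi_v <- work_function(map, base, rpot, val)
  # an estimator without overlap at this event yields an NA record
  safe <- function(expr, label, split = NA_character_) {
    tryCatch(expr, error = function(e) {
      fe_estimate(NA_real_, NA_real_, label, split)
    })
  }
  ests <- list(
    safe(estimate_AV(phi_t, split = "T"), "AVMD", "T"),
    safe(estimate_AV(phi_v, split = "V"), "AVMD", "V"),
    safe(estimate_AV(phi_q), "AVBG"),
    safe(estimate_EXP(phi_t, "MD", split = "T"), "EXPMD", "T"),
    safe(estimate_EXP(phi_v, "MD", split = "V"), "EXPMD", "V"),
    safe(estimate_EXP(phi_q, "BG"), "EXPBG"),
    safe(estimate_BAR(phi_t, phi_q, split = "T"), "BAR", "T"),
    safe(estimate_BAR(phi_v, phi_q, split = "V"), "BAR", "V"))
  sanity <- if (!is.null(pot)) {
    energy_sanity_fraction(ms, pot)
  } else {
    NA_real_
  }
  list(estimates = ests, sanity = sanity, model_samples = ms)
}

#' Train a flow on one metastable state
#'
#' Minimizes the negative mean log-likelihood ([ml_loss()]) by Adam
#' on without-replacement batches.  At every evaluation stride the
#' six-estimator sweep is run on the training split, the validation
#' split and fresh model samples; if `swap_at` is set, the splits
#' are exchanged at that batch and the parameters are reset to their
#' initial values.  Fully deterministic given the config seed.
#'
#' @param train,val disjoint, equally sized `sample_batch`es (or
#'   matrices) of MD-origin samples from the state.
#' @param rpot the state's [restricted_potential()] (used by the
#'   estimator sweep; may be `NULL` to record losses only).
#' @param config a [train_config()].
#' @param n_layers,n_bins,hidden flow architecture (see
#'   [flow_create()]).
#' @param n_model model samples drawn at each evaluation event
#'   (default 1000).
#' @param hook optional callback `function(event)` invoked at every
#'   evaluation event with the event record (batch index, map,
#'   estimates, losses).
#' @return list with the trained `map` and `trace`, a data frame of
#'   per-event rows (batch, estimator, split, value, stderr) plus
#'   loss and sanity rows.
#' @export
train_state_model <- function(train, val, rpot, config,
                              n_layers = 4L, n_bins = 16L, hidden = 64L,
                              n_model = 1000L, hook = NULL) {
  Xt <- batch_coords(train)
  Xv <- batch_coords(val)
  if (nrow(Xt) == 0L || nrow(Xv) == 0L) stop("empty split")
  stopifnot(ncol(Xt) == ncol(Xv))
  D <- ncol(Xt)
  pot <- if (!is.null(rpot)) rpot$pot else NULL
  tr <- trainer_create(Xt, config, D, n_layers = n_layers,
                       n_bins = n_bins, hidden = hidden)
  base <- tr$base
  rows <- list()
  ev <- 0L
  for (b in seq_len(config$total_batches)) {
    tr <- trainer_step(tr)
    # evaluate first: the event at the swap batch measures the
    # trained first-half model, then the splits are exchanged and
    # the parameters reset
    do_swap <- !is.null(config$swap_at) && b == config$swap_at
    if (b %% config$eval_stride == 0L) {
      ev <- ev + 1L
      res <- NULL
      if (!is.null(rpot)) {
        res <- evaluate_state_estimators(
          tr$map, base, rpot, Xt, Xv, n_model = n_model,
          seed = split_seed(config$seed, 2000L + ev), pot = pot)
        for (e in res$estimates) {
          rows[[length(rows) + 1L]] <- data.frame(
            batch = b, estimator = e$estimator,
            split = ifelse(is.na(e$split), "", e$split),
            value = e$value, stderr = e$stderr)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          batch = b, estimator = "energy_sanity", split = "",
          value = res$sanity, stderr = 0)
      }
      loss_t <- ml_loss(tr$map, base, Xt)
      loss_v <- ml_loss(tr$map, base, Xv)
      rows[[length(rows) + 1L]] <- data.frame(
        batch = b, estimator = "ml_loss", split = "T",
        value = loss_t, stderr = 0)
      rows[[length(rows) + 1L]] <- data.frame(
        batch = b, estimator = "ml_loss", split = "V",
        value = loss_v, stderr = 0)
      if (!is.null(hook)) {
        hook(list(batch = b, map = tr$map, result = res,
                  loss_train = loss_t, loss_val = loss_v))
      }
    }
    if (do_swap) {
      tmp <- Xt; Xt <- Xv; Xv <- tmp
      tr <- trainer_swap(tr, Xt)
    }
  }
  list(map = tr$map, trace = do.call(rbind, rows))
}
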