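# End-to-end convergence study on the narrow-well toy system: train
# one flow per metastable state, evaluate all six estimators on the
# training and validation splits (and fresh model samples) at every
# stride, compare against quadrature ground truth, and report
# overfitting diagnostics.

#' Study configuration
#'
#' @param system a `toy_system` (default [default_toy_system()]).
#' @param n_train,n_val per-state sample counts for the training and
#'   validation splits (default 1000 each).
#' @param train a [train_config()].
#' @param estimators subset of the six estimator labels to record
#'   (all by default; MBAR requires at least two states).
#' @param truth `"quadrature"` (default) or `"none"`.
#' @param grid_n quadrature resolution (default 128).
#' @param n_model model samples per evaluation event (default 1000).
#' @param n_layers,n_bins,hidden flow architecture defaults.
#' @param out_dir optional output directory for trace/report files.
#' @param seed master seed; all stage seeds derive from it via
#'   [split_seed()].
#' @return object of class `study_config`.
#' @export
study_config <- function(system = default_toy_system(),
                         n_train = 1000L, n_val = 1000L,
                         train = train_config(total_batches = 2000L,
                                              swap_at = 1000L),
                         estimators = c("AVMD", "AVBG", "EXPMD",
                                        "EXPBG", "BAR", "MBAR"),
                         truth = c("quadrature", "none"),
                         grid_n = 128L, n_model = 1000L,
                         n_layers = 4L, n_bins = 16L, hidden = 64L,
                         out_dir = NULL, seed = 1L) {
  truth <- match.arg(truth)
  bad <- setdiff(estimators, c("AVMD", "AVBG", "EXPMD", "EXPBG",
                               "BAR", "MBAR"))
  if (length(bad)) stop("unknown estimators: ", paste(bad, collapse = ", "))
  structure(list(system = system, n_train = as.integer(n_train),
                 n_val = as.integer(n_val), train = train,
                 estimators = estimators, truth = truth,
                 grid_n = as.integer(grid_n), n_model = as.integer(n_model),
                 n_layers = as.integer(n_layers), n_bins = as.integer(n_bins),
                 hidden = as.integer(hidden),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "study_config")
}

# quadrature state statistics: free energy and mean reduced energy
# (for the entropy ground truth s_i = <u_i> - f_i)
quad_state_stats <- function(sys, grid_n = 128L) {
  pot <- sys$pot
  g <- pot$a + (pot$b - pot$a) * (seq_len(grid_n) - 0.5) / grid_n
  dv <- ((pot$b - pot$a) / grid_n)^pot$D
  plane <- as.matrix(expand.grid(x1 = g, x2 = g))
  K <- sys$assigner$n_states
  lZ <- matrix(-Inf, grid_n, K) # per-slice log partial sums
  lU <- matrix(-Inf, grid_n, K) # per-slice log sum u * exp(-u) (u shifted > 0)
  ushift <- min(sys$depth) - 1 # keep u - ushift strictly positive
  for (s in seq_len(grid_n)) {
    S <- cbind(plane, x3 = g[s])
    u <- rp_eval(pot, S)
    lab <- assign_cluster(sys$assigner, S)
    for (i in seq_len(K)) {
      ui <- u[lab == i]
      if (length(ui)) {
        lZ[s, i] <- logsumexp(-ui)
        lU[s, i] <- logsumexp(log(ui - ushift) - ui)
      }
    }
  }
  f <- -(apply(lZ, 2L, logsumexp) + log(dv))
  umean <- exp(apply(lU, 2L, logsumexp) - apply(lZ, 2L, logsumexp)) + ushift
  delta_f <- outer(f, f, function(a, b) b - a)
  C <- outer(umean, umean, function(a, b) b - a)
  list(f = f, u_mean = umean, delta_f = delta_f,
       delta_s = C - delta_f)
}

#' Run the toy-model convergence study
#'
#' Samples training and validation sets for each of the three
#' metastable states, trains the three flows in lockstep, and at
#' every evaluation stride records all requested estimators (each on
#' the training split, the validation split and/or fresh model
#' samples), the entropy decompositions based on BAR and MBAR, the
#' training losses and the model energy-sanity fraction.  Ground
#' truth is computed by quadrature.  Everything derives
#' deterministically from the master seed.
#'
#' @param config a [study_config()].
#' @return list with `trace` (data frame: batch, target, estimator,
#'   split, value, stderr), `truth` (per-state f, pairwise
#'   differences, entropy differences), `maps`, `diagnostics`,
#'   `summary` (from [compare_to_truth()]) and `report`.
#' @export
run_toy_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  sys <- config$system
  K <- sys$assigner$n_states
  tc <- config$train
  master <- config$seed
  # stage 1: locally ergodic sample sets
  tr_sets <- lapply(seq_len(K), function(s) {
    sample_state(sys, s, config$n_train, seed = split_seed(master, 10L + s))
  })
  va_sets <- lapply(seq_len(K), function(s) {
    sample_state(sys, s, config$n_val, seed = split_seed(master, 20L + s))
  })
  # stage 2: ground truth
  truth <- if (config$truth == "quadrature") {
    quad_state_stats(sys, config$grid_n)
  } else {
    NULL
  }
  # stage 3: trainers
  rpots <- lapply(seq_len(K), function(s) {
    restricted_potential(sys$pot, s, sys$assigner)
  })
  Xt <- lapply(tr_sets, batch_coords)
  Xv <- lapply(va_sets, batch_coords)
  trainers <- lapply(seq_len(K), function(s) {
    cfg_s <- tc
    cfg_s$seed <- split_seed(master, 30L + s)
    trainer_create(Xt[[s]], cfg_s, sys$D, sys$a, sys$b,
                   n_layers = config$n_layers, n_bins = config$n_bins,
                   hidden = config$hidden)
  })
  base <- trainers[[1L]]$base
  want <- config$estimators
  rows <- list()
  add_row <- function(batch, target, estimator, split, value, stderr) {
    rows[[length(rows) + 1L]] <<- data.frame(
      batch = batch, target = target, estimator = estimator,
      split = split, value = value, stderr = stderr,
      stringsAsFactors = FALSE)
  }
  ev <- 0L
  for (b in seq_len(tc$total_batches)) {
    for (s in seq_len(K)) trainers[[s]] <- trainer_step(trainers[[s]])
    # the evaluation event at the swap batch still measures the
    # fully trained first-half models; the splits are exchanged and
    # the parameters reset immediately afterwards
    do_swap <- !is.null(tc$swap_at) && b == tc$swap_at
    if (b %% tc$eval_stride == 0L) {
      ev <- ev + 1L
      maps <- lapply(trainers, `[[`, "map")
      bar_f <- matrix(NA_real_, K, 2L) # per state, T/V
      bar_se <- matrix(NA_real_, K, 2L)
      for (s in seq_len(K)) {
        res <- evaluate_state_estimators(
          maps[[s]], base, rpots[[s]], Xt[[s]], Xv[[s]],
          n_model = config$n_model,
          seed = split_seed(master, 50000L + 100L * ev + s),
          pot = sys$pot)
        for (e in res$estimates) {
          if (!(e$estimator %in% want)) next
          add_row(b, as.character(s), e$estimator,
                  ifelse(is.na(e$split), "", e$split), e$value, e$stderr)
          if (e$estimator == "BAR") {
            j <- match(e$split, c("T", "V"))
            bar_f[s, j] <- e$value
            bar_se[s, j] <- e$stderr
          }
        }
        add_row(b, as.character(s), "energy_sanity", "", res$sanity, 0)
        add_row(b, as.character(s), "ml_loss", "T",
                ml_loss(maps[[s]], base, Xt[[s]]), 0)
        add_row(b, as.character(s), "ml_loss", "V",
                ml_loss(maps[[s]], base, Xv[[s]]), 0)
      }
      # entropy decomposition via BAR (energies from the matching split)
      en_t <- lapply(seq_len(K), function(s) rp_eval(sys$pot, Xt[[s]]))
      en_v <- lapply(seq_len(K), function(s) rp_eval(sys$pot, Xv[[s]]))
      if ("BAR" %in% want) {
        for (j in 1:2) {
          en <- if (j == 1L) en_t else en_v
          df <- outer(bar_f[, j], bar_f[, j], function(a, bb) bb - a)
          dfse <- sqrt(outer(bar_se[, j]^2, bar_se[, j]^2, "+"))
          diag(dfse) <- 0
          ed <- entropy_decomposition(df, dfse, en)
          for (i in seq_len(K - 1L)) for (jj in (i + 1L):K) {
            add_row(b, paste0(i, "-", jj), "dS_BAR", c("T", "V")[j],
                    ed$delta_s[i, jj], ed$stderr[i, jj])
          }
        }
      }
      if ("MBAR" %in% want && K >= 2L) {
        for (j in 1:2) {
          sets <- if (j == 1L) Xt else Xv
          en <- if (j == 1L) en_t else en_v
          batches <- lapply(seq_len(K), function(s) {
            sample_batch(sets[[s]], origin = "md", state = s)
          })
          # very early in training the composed maps may not yet
          # transport any mass between states: no overlap, no
          # estimate -- recorded as NA rows
          mb <- tryCatch(estimate_MBAR(maps, rpots, batches,
                                       split = c("T", "V")[j]),
                         error = function(e) NULL)
          if (is.null(mb)) {
            for (i in seq_len(K - 1L)) for (jj in (i + 1L):K) {
              add_row(b, paste0(i, "-", jj), "MBAR", c("T", "V")[j],
                      NA_real_, NA_real_)
              add_row(b, paste0(i, "-", jj), "dS_MBAR", c("T", "V")[j],
                      NA_real_, NA_real_)
            }
            next
          }
          df <- outer(mb$f, mb$f, function(a, bb) bb - a)
          dfse <- matrix(0, K, K)
          for (i in seq_len(K)) for (jj in seq_len(K)) {
            dfse[i, jj] <- sqrt(max(mb$covariance[i, i] +
                                      mb$covariance[jj, jj] -
                                      2 * mb$covariance[i, jj], 0))
          }
          ed <- entropy_decomposition(df, dfse, en)
          for (nm in names(mb$pairs)) {
            p <- mb$pairs[[nm]]
            add_row(b, nm, "MBAR", c("T", "V")[j], p$value, p$stderr)
          }
          for (i in seq_len(K - 1L)) for (jj in (i + 1L):K) {
            add_row(b, paste0(i, "-", jj), "dS_MBAR", c("T", "V")[j],
                    ed$delta_s[i, jj], ed$stderr[i, jj])
          }
        }
      }
    }
    if (do_swap) {
      tmp <- Xt; Xt <- Xv; Xv <- tmp
      for (s in seq_len(K)) {
        trainers[[s]] <- trainer_swap(trainers[[s]], Xt[[s]])
      }
    }
  }
  trace <- do.call(rbind, rows)
  diagnostics <- overfit_diagnostics(trace)
  summary <- if (!is.null(truth)) compare_to_truth(trace, truth) else NULL
  rep <- study_report(trace, diagnostics, summary)
  out <- list(trace = trace, truth = truth,
              maps = lapply(trainers, `[[`, "map"),
              train_sets = tr_sets, val_sets = va_sets,
              diagnostics = diagnostics, summary = summary, report = rep,
              config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trace(trace, file.path(config$out_dir, "trace.csv"))
    jsonlite::write_json(rep, file.path(config$out_dir, "report.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE,
                         force = TRUE)
    # terminal pairwise matrices (from the trace rows of the last event)
    for (est in intersect(c("MBAR", "dS_MBAR"), unique(trace$estimator))) {
      sub <- trace[trace$estimator == est & trace$split == "V" &
                     trace$batch == max(trace$batch), , drop = FALSE]
      if (!nrow(sub)) next
      m <- matrix(0, K, K)
      mse <- matrix(0, K, K)
      for (r in seq_len(nrow(sub))) {
        ij <- as.integer(strsplit(sub$target[r], "-")[[1]])
        m[ij[1], ij[2]] <- sub$value[r]
        m[ij[2], ij[1]] <- -sub$value[r]
        mse[ij[1], ij[2]] <- mse[ij[2], ij[1]] <- sub$stderr[r]
      }
      nm <- if (est == "MBAR") "delta_f" else "delta_s"
      utils::write.csv(m, file.path(config$out_dir,
                                    paste0(nm, "_mbar_v.csv")),
                       row.names = FALSE)
      utils::write.csv(mse, file.path(config$out_dir,
                                      paste0(nm, "_mbar_v_stderr.csv")),
                       row.names = FALSE)
    }
  }
  out
}

#' Compare a convergence trace with ground truth
#'
#' For every estimator x split x target present in the trace,
#' computes the fraction of post-burn-in evaluation events whose
#' estimate brackets the ground truth within twice its analytic
#' standard error, together with the terminal bias and terminal
#' standard error.  The first 10% of events are discarded as
#' burn-in.
#'
#' @param trace trace data frame from [run_toy_study()].
#' @param truth list with per-state `f` and matrices `delta_f`,
#'   `delta_s` (as from the quadrature stage).
#' @param burn_frac fraction of initial events excluded (default
#'   0.1).
#' @return data frame with columns estimator, split, target,
#'   coverage, terminal_bias, terminal_stderr, n_events.
#' @export
compare_to_truth <- function(trace, truth, burn_frac = 0.1) {
  if (is.null(truth)) stop("no ground truth")
  truth_of <- function(target, estimator) {
    if (grepl("^dS", estimator)) {
      ij <- as.integer(strsplit(target, "-")[[1]])
      truth$delta_s[ij[1], ij[2]]
    } else if (grepl("-", target, fixed = TRUE)) {
      ij <- as.integer(strsplit(target, "-")[[1]])
      truth$delta_f[ij[1], ij[2]]
    } else {
      truth$f[as.integer(target)]
    }
  }
  keep <- !(trace$estimator %in% c("ml_loss", "energy_sanity"))
  tr <- trace[keep, , drop = FALSE]
  out <- list()
  for (key in unique(paste(tr$estimator, tr$split, tr$target, sep = "|"))) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    sub <- tr[tr$estimator == parts[1] &
                tr$split == ifelse(length(parts) >= 2, parts[2], "") &
                tr$target == parts[3], , drop = FALSE]
    sub <- sub[order(sub$batch), , drop = FALSE]
    n_ev <- nrow(sub)
    n_burn <- floor(burn_frac * n_ev)
    post <- if (n_burn > 0L) sub[-seq_len(n_burn), , drop = FALSE] else sub
    tv <- truth_of(parts[3], parts[1])
    # events without an estimate (no overlap yet) count as not
    # covering the truth
    hit <- abs(post$value - tv) <= 2 * post$stderr
    hit[is.na(hit)] <- FALSE
    cov <- mean(hit)
    ok <- which(!is.na(post$value))
    last <- post[if (length(ok)) max(ok) else nrow(post), ]
    out[[length(out) + 1L]] <- data.frame(
      estimator = parts[1], split = parts[2], target = parts[3],
      truth = tv, coverage = cov,
      terminal_bias = last$value - tv, terminal_stderr = last$stderr,
      n_events = n_ev, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Overfitting diagnostics from a convergence trace
#'
#' Implements the heuristics usable without ground truth:
#' (a) the batch index maximizing the validation work-function
#' average AVMD_V per state -- the early-stopping suggestion;
#' (b) the BAR/MBAR validation-stderr series with a monotone-growth
#' flag (rank correlation with training progress > 0.6 and
#' last-quarter median more than 1.5x the first-quarter median);
#' (c) the train-vs-validation estimate gap series per estimator.
#'
#' @param trace trace data frame (needs >= 2 evaluation events).
#' @return list with `avmdv_argmax`, `stderr_growth`, `gap_series`.
#' @export
overfit_diagnostics <- function(trace) {
  if (length(unique(trace$batch)) < 2L) {
    stop("need at least 2 evaluation events")
  }
  av <- trace[trace$estimator == "AVMD" & trace$split == "V", , drop = FALSE]
  avmdv_argmax <- if (nrow(av)) {
    do.call(rbind, lapply(split(av, av$target), function(s) {
      data.frame(target = s$target[1],
                 batch = s$batch[which.max(s$value)],
                 value = max(s$value), stringsAsFactors = FALSE)
    }))
  } else {
    NULL
  }
  growth <- list()
  for (est in c("BAR", "MBAR")) {
    sub <- trace[trace$estimator == est & trace$split == "V", , drop = FALSE]
    for (tg in unique(sub$target)) {
      s <- sub[sub$target == tg, , drop = FALSE]
      s <- s[order(s$batch), ]
      n <- nrow(s)
      if (n < 8L) next
      q1 <- stats::median(s$stderr[seq_len(ceiling(n / 4))])
      q4 <- stats::median(s$stderr[(n - ceiling(n / 4) + 1L):n])
      rho <- suppressWarnings(
        stats::cor(seq_len(n), s$stderr, method = "spearman"))
      growth[[paste0(est, "_", tg)]] <- data.frame(
        estimator = est, target = tg, rho = rho,
        ratio = q4 / q1,
        flag = isTRUE(rho > 0.6 && q4 > 1.5 * q1),
        stringsAsFactors = FALSE)
    }
  }
  gap <- list()
  core <- trace[trace$estimator %in% c("AVMD", "EXPMD", "BAR", "MBAR",
                                       "dS_BAR", "dS_MBAR"), , drop = FALSE]
  for (key in unique(paste(core$estimator, core$target, sep = "|"))) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    st <- core[core$estimator == parts[1] & core$target == parts[2] &
                 core$split == "T", , drop = FALSE]
    sv <- core[core$estimator == parts[1] & core$target == parts[2] &
                 core$split == "V", , drop = FALSE]
    if (!nrow(st) || !nrow(sv)) next
    m <- merge(st[, c("batch", "value")], sv[, c("batch", "value")],
               by = "batch", suffixes = c("_T", "_V"))
    gap[[key]] <- data.frame(estimator = parts[1], target = parts[2],
                             batch = m$batch,
                             gap = m$value_T - m$value_V,
                             stringsAsFactors = FALSE)
  }
  list(avmdv_argmax = avmdv_argmax,
       stderr_growth = if (length(growth)) do.call(rbind, growth) else NULL,
       gap_series = if (length(gap)) do.call(rbind, gap) else NULL)
}

#' Assemble the study report
#'
#' A machine-readable summary of a convergence study: per-estimator
#' coverage and terminal bias (when ground truth is available),
#' early-stopping suggestions, stderr-growth flags and final
#' energy-sanity fractions.  Every number is taken from the trace or
#' the comparison table; nothing is recomputed.
#'
#' @param trace trace data frame.
#' @param diagnostics output of [overfit_diagnostics()].
#' @param summary output of [compare_to_truth()] (or `NULL`).
#' @return list (JSON-serializable) with a `flags` element that is
#'   empty when no overfitting indicators fired.
#' @export
study_report <- function(trace, diagnostics, summary = NULL) {
  flags <- list()
  if (!is.null(diagnostics$stderr_growth)) {
    g <- diagnostics$stderr_growth
    for (i in seq_len(nrow(g))) {
      if (g$flag[i]) {
        flags[[length(flags) + 1L]] <- sprintf(
          "%s_V stderr growing on %s (rho=%.2f, ratio=%.2f)",
          g$estimator[i], g$target[i], g$rho[i], g$ratio[i])
      }
    }
  }
  sane <- trace[trace$estimator == "energy_sanity", , drop = FALSE]
  sanity_final <- if (nrow(sane)) {
    s <- sane[sane$batch == max(sane$batch), ]
    stats::setNames(s$value, paste0("state_", s$target))
  } else {
    NULL
  }
  list(schema = "flowfe-report", version = 1L,
       n_events = length(unique(trace$batch)),
       last_batch = max(trace$batch),
       early_stop = diagnostics$avmdv_argmax,
       flags = if (length(flags)) unlist(flags) else character(0),
       energy_sanity_final = as.list(sanity_final),
       summary = summary)
}
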