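# Poisson-likelihood training with the warm-restart cosine schedule, and
# frozen-core transfer to new sessions.

#' Poisson negative log-likelihood
#'
#' `sum_i (r_i - y_i log r_i)` over all elements; the `y = 0` convention is
#' that such terms contribute `r` only.
#'
#' @param r Predicted responses (> 0).
#' @param y Observed responses (>= 0).
#' @return Scalar loss.
#' @export
poisson_loss <- function(r, y) {
  if (any(r <= 0)) stop("predicted responses must be strictly positive", call. = FALSE)
  lr <- log(r)
  lr[y == 0] <- 0 # avoid 0 * -Inf when r underflows; y=0 contributes r only
  sum(r - y * lr)
}

#' Training configuration
#'
#' The full-scale schedule: 200 epochs of 512 iterations, batches of 5 clips
#' of 70 frames, learning rate linearly warmed up over the first 10 epochs,
#' cosine-decayed to 0 over the next 90, warm-restarted to the base rate at
#' epoch 100 and cosine-decayed over the remaining 100. Optimized with SGD +
#' Nesterov momentum. [desk_train_config()] shrinks the schedule with the
#' same piecewise shape.
#'
#' @param epochs,iters_per_epoch,batch_size,clip_frames Schedule sizes.
#' @param warmup_epochs,first_cosine_epochs,second_cosine_epochs Phase
#'   lengths; must sum to `epochs`.
#' @param base_lr Peak learning rate.
#' @param momentum Nesterov momentum coefficient.
#' @param clip_grad_norm Global gradient-norm clip (Inf disables).
#' @param mode `"full"` (all modules trained) or `"transfer"` (core frozen).
#' @param seed RNG seed for clip sampling and readout position noise.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 200L, iters_per_epoch = 512L, batch_size = 5L,
                         clip_frames = 70L, warmup_epochs = 10L,
                         first_cosine_epochs = 90L, second_cosine_epochs = 100L,
                         base_lr = 0.02, momentum = 0.9, clip_grad_norm = 20,
                         mode = c("full", "transfer"), seed = 1L) {
  mode <- match.arg(mode)
  if (warmup_epochs + first_cosine_epochs + second_cosine_epochs != epochs) {
    stop("warmup + first + second cosine epochs must equal epochs", call. = FALSE)
  }
  structure(list(epochs = as.integer(epochs),
                 iters_per_epoch = as.integer(iters_per_epoch),
                 batch_size = as.integer(batch_size),
                 clip_frames = as.integer(clip_frames),
                 warmup_epochs = as.integer(warmup_epochs),
                 first_cosine_epochs = as.integer(first_cosine_epochs),
                 second_cosine_epochs = as.integer(second_cosine_epochs),
                 base_lr = base_lr, momentum = momentum,
                 clip_grad_norm = clip_grad_norm, mode = mode,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training configuration
#'
#' The 200-epoch schedule shrunk to single-CPU scale with the same piecewise
#' shape (5% warmup, 45% first cosine, 50% post-restart cosine).
#'
#' @param ... Overrides passed to [train_config()].
#' @export
desk_train_config <- function(...) {
  defaults <- list(epochs = 20L, iters_per_epoch = 12L, batch_size = 2L,
                   clip_frames = 16L, warmup_epochs = 1L,
                   first_cosine_epochs = 9L, second_cosine_epochs = 10L)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(train_config, defaults)
}

#' Learning rate at a given epoch and iteration
#'
#' Piecewise schedule at iteration granularity: linear warmup from 0 to
#' `base_lr` over the warmup epochs; cosine decay to 0 over the first cosine
#' phase; an instantaneous warm restart to `base_lr`; cosine decay to 0 over
#' the second phase.
#'
#' @param epoch 0-based epoch index in `[0, epochs)`.
#' @param iter 0-based iteration within the epoch.
#' @param cfg A [train_config()].
#' @return The learning rate.
#' @export
lr_at <- function(epoch, iter, cfg) {
  if (epoch < 0 || epoch >= cfg$epochs) stop("epoch out of range", call. = FALSE)
  e <- epoch + iter / cfg$iters_per_epoch
  w <- cfg$warmup_epochs; f1 <- cfg$first_cosine_epochs; f2 <- cfg$second_cosine_epochs
  if (e < w) return(cfg$base_lr * e / w)
  if (e < w + f1) return(cfg$base_lr * (1 + cos(pi * (e - w) / f1)) / 2)
  cfg$base_lr * (1 + cos(pi * (e - w - f1) / f2)) / 2
}

transfer_trainable <- function(path) {
  # core = feedforward blocks + recurrent cells, frozen during transfer
  !grepl("^heads\\.[0-9]+\\.(ff|cells)\\.", path)
}

clip_window_starts <- function(session, clip_frames) {
  tr <- session$trials[session$trials$split == "train", , drop = FALSE]
  starts <- integer(0)
  for (i in seq_len(nrow(tr))) {
    if (tr$offset_frame[i] - tr$onset_frame[i] + 1L >= clip_frames) {
      starts <- c(starts, tr$onset_frame[i]:(tr$offset_frame[i] - clip_frames + 1L))
    }
  }
  if (length(starts) == 0) stop("no training window of the requested length", call. = FALSE)
  starts
}

set_session_norm <- function(model, session) {
  idx <- split_frames(session, "train")
  b <- session$behavior
  model$norm <- list(
    pupil_mean = colMeans(b$pupil_xy[idx, , drop = FALSE]),
    pupil_sd = pmax(apply(b$pupil_xy[idx, , drop = FALSE], 2, stats::sd), 1e-6),
    behav_mean = c(mean(b$treadmill[idx]), mean(b$pupil[idx]), mean(b$pupil_d[idx])),
    behav_sd = pmax(c(stats::sd(b$treadmill[idx]), stats::sd(b$pupil[idx]),
                      stats::sd(b$pupil_d[idx])), 1e-6))
  model
}

slice_behavior <- function(behavior, idx) {
  list(treadmill = behavior$treadmill[idx], pupil = behavior$pupil[idx],
       pupil_d = behavior$pupil_d[idx])
}

# mean/sd of log-responses per neuron per head over a sample of training
# frames, for ensemble standardization
compute_train_stats <- function(model, session, max_frames = 960L, chunk = 96L) {
  idx <- split_frames(session, "train")
  if (length(idx) > max_frames) idx <- idx[seq_len(max_frames)]
  logs <- rep(list(NULL), model$config$heads)
  for (c0 in seq(1L, length(idx), by = chunk)) {
    sub <- idx[c0:min(length(idx), c0 + chunk - 1L)]
    out <- encoder_forward(model, session$stimulus$frames[sub, , , drop = FALSE],
                           slice_behavior(session$behavior, sub),
                           session$behavior$pupil_xy[sub, , drop = FALSE])
    for (h in seq_len(model$config$heads)) {
      logs[[h]] <- rbind(logs[[h]], log(out$rates[, , h]))
    }
  }
  lapply(logs, function(L) list(mean = colMeans(L), sd = apply(L, 2, stats::sd)))
}

#' Train an encoder on a session
#'
#' Minimizes the Poisson negative log-likelihood of the recorded responses
#' by SGD with Nesterov momentum under the warm-restart cosine schedule.
#' Each iteration draws `batch_size` random `clip_frames`-frame windows from
#' the training split; readout positions are sampled per clip through the
#' reparameterization trick. In `"transfer"` mode the core (feedforward +
#' recurrent cells) is excluded from the update; perspective, modulation and
#' readout are fitted. Fully seeded: the same seed reproduces the parameter
#' trajectory.
#'
#' @param model An `encoder_model` from [encoder_init()].
#' @param session A `session_bundle` with a training split.
#' @param cfg A [train_config()].
#' @param train_fraction Fraction (0, 1] of the training windows used
#'   (earliest portion), emulating restricted training data.
#' @param verbose Print per-epoch mean loss.
#' @return The fitted model, with `history` (data frame: epoch, iter, lr,
#'   loss per frame-neuron) attached.
#' @export
train_model <- function(model, session, cfg = desk_train_config(),
                        train_fraction = 1, verbose = FALSE) {
  stopifnot(inherits(model, "encoder_model"), inherits(session, "session_bundle"))
  model <- set_session_norm(model, session)
  y_all <- session$responses
  starts <- clip_window_starts(session, cfg$clip_frames)
  if (train_fraction < 1) {
    keep <- max(1L, floor(length(starts) * train_fraction))
    starts <- starts[seq_len(keep)]
  }
  # start readout biases at the per-neuron mean log-rate so the Poisson
  # surface is well-scaled from the first iteration
  mean_rate <- pmax(colMeans(y_all[split_frames(session, "train"), , drop = FALSE]), 1e-3)
  for (h in seq_len(model$config$heads)) {
    model$params$heads[[h]]$readout$b <- log(mean_rate)
  }
  trainable <- if (cfg$mode == "transfer") transfer_trainable else function(p) TRUE
  # shared parameters accumulate gradients summed over all neurons while
  # per-neuron readout parameters see only their own loss terms; normalize
  # each parameter's gradient by the number of neurons it serves so one
  # learning rate fits both groups
  all_paths <- vapply(flatten_params(model$params), function(l) l$path, "")
  shared_scale <- ifelse(grepl("^heads\\.[0-9]+\\.readout", all_paths),
                         1, 1 / model$n_neurons)
  # readout positions live in normalized [-1,1] units and their gradients
  # carry the growing feature weights; damp them for stability
  shared_scale[grepl("^readout_pos", all_paths)] <- 0.1
  history <- vector("list", cfg$epochs * cfg$iters_per_epoch)
  hi <- 0L
  opt_state <- NULL
  with_preserved_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs) - 1L) {
      ep_loss <- 0
      for (iter in seq_len(cfg$iters_per_epoch) - 1L) {
        lr <- lr_at(epoch, iter, cfg)
        g <- ag_graph()
        pt <- wrap_params(model$params, g, trainable)
        leaves <- collect_tensors(pt)
        is_par <- vapply(leaves, function(t) !is.null(t$graph) && is.null(t$backward), TRUE)
        pars <- leaves[is_par]
        par_scale <- shared_scale[is_par]
        if (is.null(opt_state)) opt_state <- sgd_state_new(pars)
        batch_starts <- sample(starts, cfg$batch_size, replace = TRUE)
        loss <- NULL
        for (s0 in batch_starts) {
          idx <- s0:(s0 + cfg$clip_frames - 1L)
          eps <- matrix(stats::rnorm(2 * model$n_neurons), model$n_neurons, 2)
          out <- encoder_forward(model, session$stimulus$frames[idx, , , drop = FALSE],
                                 slice_behavior(session$behavior, idx),
                                 session$behavior$pupil_xy[idx, , drop = FALSE],
                                 pt = pt, mode = "train", pos_eps = eps)
          yv <- as.vector(y_all[idx, , drop = FALSE]) # t-fastest, matches r
          for (h in seq_len(model$config$heads)) {
            r <- out$head_tensors[[h]]
            l_h <- ag_sum(ag_sub(r, ag_mul(ag_log(r), yv)))
            loss <- if (is.null(loss)) l_h else ag_add(loss, l_h)
          }
        }
        # per-frame normalization only: the loss stays a sum over neurons so
        # each neuron's readout receives a full-sized gradient
        denom <- cfg$batch_size * cfg$clip_frames * model$config$heads
        loss_val <- ag_val(loss) / denom
        if (!is.finite(loss_val)) {
          stop(sprintf("non-finite training loss at epoch %d iter %d; try a lower base_lr",
                       epoch, iter), call. = FALSE)
        }
        ag_backward(loss, seed_grad = 1 / denom)
        opt_state <- sgd_step(pars, opt_state, lr, cfg$momentum, cfg$clip_grad_norm,
                              grad_scale = par_scale)
        # persist updated values back into the model
        model$params <- unwrap_params(pt)
        ep_loss <- ep_loss + loss_val
        hi <- hi + 1L
        history[[hi]] <- data.frame(epoch = epoch, iter = iter, lr = lr,
                                    loss = loss_val / model$n_neurons)
      }
      if (verbose) {
        message(sprintf("epoch %3d  lr %.4g  loss %.4f", epoch,
                        lr_at(epoch, 0, cfg), ep_loss / cfg$iters_per_epoch))
      }
    }
  })
  model$history <- do.call(rbind, history[seq_len(hi)])
  model$train_stats <- compute_train_stats(model, session)
  model
}

#' Transfer a frozen core to a new session
#'
#' Builds a model for the new session that reuses the foundation model's
#' core parameters (feedforward and recurrent cells of every head) and
#' freshly initializes perspective, modulation and readout, then fits only
#' those components (`mode = "transfer"`). The core is bit-identical before
#' and after.
#'
#' @param foundation A trained `encoder_model` (the foundation core donor).
#' @param session The new session.
#' @param cfg A [train_config()]; its `mode` is forced to `"transfer"`.
#' @param train_fraction Fraction of the new session's training data to use.
#' @param seed Seed for the fresh non-core parameters.
#' @return The fitted transfer model.
#' @export
transfer_model <- function(foundation, session, cfg = desk_train_config(),
                           train_fraction = 1, seed = 1L) {
  cfg$mode <- "transfer"
  model <- encoder_init(foundation$config, ncol(session$responses),
                        mon = session$monitor, seed = seed)
  for (h in seq_len(model$config$heads)) {
    model$params$heads[[h]]$ff <- foundation$params$heads[[h]]$ff
    model$params$heads[[h]]$cells <- foundation$params$heads[[h]]$cells
  }
  train_model(model, session, cfg, train_fraction = train_fraction)
}

#' Evaluate a model on a session's repeated test clips
#'
#' Predicts responses for every repeat of the held-out test clips (each
#' repeat with its own behaviour), averages the predictions over repeats,
#' and computes per-neuron CC metrics against the observed repeats.
#'
#' @param model A trained `encoder_model`.
#' @param session The session.
#' @param max_pred_repeats Repeats actually predicted (their behaviours
#'   differ; the average over a few repeats estimates the mean prediction
#'   at a fraction of the cost).
#' @param chunk Frames per forward pass (bounds memory; the recurrent state
#'   restarts per chunk, a negligible warm-up effect at this length).
#' @return List with `metrics` (per-neuron data frame) and `summary`.
#' @export
evaluate_model <- function(model, session, max_pred_repeats = 3L,
                           chunk = 150L) {
  reps <- test_repeats(session)
  use <- reps$frames_by_rep[seq_len(min(max_pred_repeats, length(reps$frames_by_rep)))]
  pred_acc <- NULL
  for (fr in use) {
    p <- NULL
    for (c0 in seq(1L, length(fr), by = chunk)) {
      sub <- fr[c0:min(length(fr), c0 + chunk - 1L)]
      p <- rbind(p, predict_responses(model,
                                      session$stimulus$frames[sub, , , drop = FALSE],
                                      slice_behavior(session$behavior, sub),
                                      session$behavior$pupil_xy[sub, , drop = FALSE]))
    }
    pred_acc <- if (is.null(pred_acc)) p else pred_acc + p
  }
  pred <- pred_acc / length(use)
  metrics <- evaluate_predictions(pred, reps$trials_list)
  list(metrics = metrics, summary = session_summary(metrics))
}
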