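# Ground-truth simulator. Generates recording sessions from neurons with
# known tuning so that every analysis in the package can be scored against
# latent truth: each neuron has a spatial receptive field on the monitor, a
# preferred motion direction with separate direction and orientation
# selectivity, a multiplicative behavioural gain and a baseline rate.
# Responses are local motion-energy rates with optional Poisson observation
# noise.

#' Generate a ground-truth neuron population
#'
#' Tuning parameters are drawn from fixed documented distributions: RF
#' centres uniform over the central 60% of the monitor (so receptive fields
#' stay on screen), RF sizes log-normal around 9 visual degrees, preferred
#' directions uniform on `[0, 2pi)`, direction selectivity Beta(1.2, 1.2),
#' orientation bandwidth uniform 0.5-1.2 rad, behaviour gains normal with
#' s.d. 0.15, baselines log-normal around 0.6. With `n_classes > 1` each
#' neuron also receives a latent feature template (its class template plus
#' noise) used by the barcode analyses.
#'
#' @param n Number of neurons.
#' @param seed RNG seed.
#' @param n_classes Latent classes for barcode structure (default 4).
#' @param class_separation Distance between class templates (default 3).
#' @param template_dim Dimensionality of latent feature templates.
#' @return A data frame of class `neuron_population` (one row per neuron)
#'   with the latent template matrix in `attr(, "templates")`.
#' @export
make_population <- function(n, seed = 1L, n_classes = 4L, class_separation = 3,
                            template_dim = 16L) {
  stopifnot(n >= 1)
  with_preserved_seed(seed, {
    pop <- data.frame(
      neuron = seq_len(n),
      rf_x = stats::runif(n, 0.2, 0.8),   # fraction of monitor width
      rf_y = stats::runif(n, 0.2, 0.8),   # fraction of monitor height (0 = top)
      rf_sigma_deg = exp(stats::rnorm(n, log(9), 0.25)),
      pref_direction = stats::runif(n, 0, 2 * pi),
      direction_selectivity = stats::rbeta(n, 1.2, 1.2),
      orientation_bandwidth = stats::runif(n, 0.5, 1.2),
      gain_treadmill = stats::rnorm(n, 0, 0.15),
      gain_pupil = stats::rnorm(n, 0, 0.15),
      baseline = exp(stats::rnorm(n, log(0.6), 0.3)),
      class = sample.int(n_classes, n, replace = TRUE)
    )
    class_templates <- matrix(stats::rnorm(n_classes * template_dim), n_classes)
    class_templates <- class_templates / sqrt(rowSums(class_templates^2)) * class_separation
    features <- class_templates[pop$class, , drop = FALSE] +
      matrix(stats::rnorm(n * template_dim), n)
    attr(pop, "templates") <- class_templates
    attr(pop, "features") <- features
    class(pop) <- c("neuron_population", "data.frame")
    pop
  })
}

# Gaussian RF weight matrix [n_neurons, n_pixels], each row sums to 1.
population_rf_weights <- function(pop, mon) {
  grid <- monitor_px_grid(mon)
  deg_per_cm <- angular_resolution(mon, 0)
  px <- as.vector(grid$x); py <- as.vector(grid$y)
  W <- matrix(0, nrow(pop), length(px))
  for (i in seq_len(nrow(pop))) {
    cx <- (pop$rf_x[i] - 0.5) * mon$width_cm
    cy <- (0.5 - pop$rf_y[i]) * mon$height_cm
    s_cm <- pop$rf_sigma_deg[i] / deg_per_cm
    w <- exp(-((px - cx)^2 + (py - cy)^2) / (2 * s_cm^2))
    W[i, ] <- w / sum(w)
  }
  W
}

#' Simulate neuronal responses to a stimulus
#'
#' The rate model is multiplicative:
#' `rate = baseline * exp(g_r r_t + g_p p_t) * tuning(theta_t) * (1 + k E_t)`
#' where `E_t` is the RF-weighted contrast energy (mean `|s - s0|` under the
#' neuron's Gaussian RF), `theta_t` is the local motion direction estimated
#' by RF-weighted Lucas-Kanade optical flow, and the tuning factor
#' `(1 + m_t ds cos(theta - pref)) * exp(-kappa_o m_t (1 - cos 2(theta - pref)))`
#' is gated by a motion-strength weight `m_t` that is 0 for static input and
#' saturates at 1, so a blank stimulus yields exactly
#' `baseline * exp(gain . behaviour)`. Poisson mode draws per-frame counts
#' at the rate.
#'
#' @param pop A `neuron_population`.
#' @param frames Stimulus array `[T, H, W]` (0-255).
#' @param behavior List with `treadmill` and `pupil_d` traces (length T);
#'   gains act on the raw treadmill speed and pupil-diameter derivative.
#' @param mon A [monitor_geometry()] matching the frames.
#' @param noise `"none"` (return the rate) or `"poisson"`.
#' @param seed RNG seed for the Poisson draw.
#' @param energy_gain Contrast-energy gain k (default 8).
#' @param motion_sat Motion strength (px/frame) at which the tuning gate
#'   saturates to 1 (default 0.05).
#' @param chunk_frames Frames processed per chunk (memory/time trade-off).
#' @return `T x N` matrix of rates or counts.
#' @export
simulate_responses <- function(pop, frames, behavior, mon = monitor_geometry(),
                               noise = c("poisson", "none"), seed = 1L,
                               energy_gain = 8, motion_sat = 0.05,
                               chunk_frames = 1024L) {
  noise <- match.arg(noise)
  T <- dim(frames)[1]
  if (length(behavior$treadmill) != T) {
    stop("misaligned behaviour and stimulus lengths", call. = FALSE)
  }
  W <- population_rf_weights(pop, mon)
  Wt <- t(W)
  N <- nrow(pop)
  h <- dim(frames)[2]; w <- dim(frames)[3]
  alpha <- 0.25 # causal temporal integration over ~4 frames
  ema_state <- matrix(0, 6, N) # E, a11, a12, a22, b1, b2
  rate <- matrix(0, T, N)
  ds_r <- pop$direction_selectivity
  ko_r <- 1 / (2 * pop$orientation_bandwidth^2)
  prev_frame <- NULL
  for (c0 in seq(1L, T, by = chunk_frames)) {
    c1 <- min(T, c0 + chunk_frames - 1L)
    idx <- c0:c1
    Tc <- length(idx)
    Sarr <- array(frames[idx, , , drop = FALSE], c(Tc, h, w)) / 255 - 0.5
    S <- matrix(Sarr, Tc, h * w)
    E0 <- abs(S) %*% Wt
    # spatial gradients (screen x right = +col, y up = -row)
    Gx <- array(0, c(Tc, h, w)); Gy <- array(0, c(Tc, h, w))
    Gx[, , 2:(w - 1)] <- (Sarr[, , 3:w] - Sarr[, , 1:(w - 2)]) / 2
    Gy[, 2:(h - 1), ] <- (Sarr[, 1:(h - 2), ] - Sarr[, 3:h, ]) / 2
    Gt <- array(0, c(Tc, h, w))
    if (Tc > 1) Gt[2:Tc, , ] <- Sarr[2:Tc, , ] - Sarr[1:(Tc - 1), , ]
    if (!is.null(prev_frame)) Gt[1, , ] <- Sarr[1, , ] - prev_frame
    prev_frame <- Sarr[Tc, , ]
    gx <- matrix(Gx, Tc, h * w); gy <- matrix(Gy, Tc, h * w); gt <- matrix(Gt, Tc, h * w)
    raw <- list(E0,
                (gx * gx) %*% Wt, (gx * gy) %*% Wt, (gy * gy) %*% Wt,
                -(gx * gt) %*% Wt, -(gy * gt) %*% Wt)
    sm <- vector("list", 6)
    for (k in 1:6) {
      m <- raw[[k]]
      sm[[k]] <- vapply(seq_len(N), function(j) {
        as.numeric(stats::filter(alpha * m[, j], 1 - alpha,
                                 method = "recursive", init = ema_state[k, j]))
      }, numeric(Tc))
      ema_state[k, ] <- sm[[k]][Tc, ]
    }
    E <- sm[[1]]; a11 <- sm[[2]]; a22 <- sm[[4]]; b1 <- sm[[5]]; b2 <- sm[[6]]
    # gradient-weighted normal-flow vector b / tr(A): for oriented content
    # the full least-squares solve amplifies noise along the weak axis of
    # the structure tensor (aperture problem), whereas the motion-energy
    # vector b points along the drift for rigidly moving patterns
    tr <- a11 + a22
    vx <- b1 / (tr + 1e-12)
    vy <- b2 / (tr + 1e-12)
    speed <- sqrt(vx^2 + vy^2)
    mgate <- pmin(speed / motion_sat, 1)
    theta <- atan2(vy, vx)
    dth <- sweep(theta, 2, pop$pref_direction, "-")
    ds <- matrix(ds_r, Tc, N, byrow = TRUE)
    ko <- matrix(ko_r, Tc, N, byrow = TRUE)
    tuning <- (1 + mgate * ds * cos(dth)) * exp(-ko * mgate * (1 - cos(2 * dth)))
    gains <- exp(outer(behavior$treadmill[idx], pop$gain_treadmill) +
                 outer(behavior$pupil_d[idx], pop$gain_pupil))
    base <- matrix(pop$baseline, Tc, N, byrow = TRUE)
    rate[idx, ] <- base * gains * tuning * (1 + energy_gain * E)
  }
  if (noise == "none") return(rate)
  with_preserved_seed(seed, {
    matrix(stats::rpois(length(rate), rate), nrow(rate), ncol(rate))
  })
}

#' Smooth stochastic behaviour traces
#'
#' Ornstein-Uhlenbeck processes: treadmill speed (softplus-rectified, so
#' rest/run epochs emerge), pupil diameter (positive, slowly varying), its
#' first-difference derivative, and a 2D pupil-centre position in arbitrary
#' camera units.
#'
#' @param n_frames Number of frames.
#' @param fps Sampling rate.
#' @param seed RNG seed.
#' @param gaze_sd S.d. of the pupil-centre excursion (camera units).
#' @return List with `treadmill`, `pupil`, `pupil_d`, `pupil_xy`.
#' @export
make_behavior <- function(n_frames, fps = 30, seed = 1L, gaze_sd = 1) {
  ou <- function(n, tau_s, sigma, mu = 0) {
    dt <- 1 / fps
    x <- numeric(n)
    x[1] <- mu + stats::rnorm(1, 0, sigma)
    k <- dt / tau_s
    for (t in 2:n) {
      x[t] <- x[t - 1] + k * (mu - x[t - 1]) + sigma * sqrt(2 * k) * stats::rnorm(1)
    }
    x
  }
  softplus <- function(x) log1p(exp(pmin(x, 30)))
  with_preserved_seed(seed, {
    tread <- softplus(ou(n_frames, 8, 1.2, mu = -0.5))
    pupil <- softplus(ou(n_frames, 15, 0.5, mu = 1))
    pupil_d <- c(0, diff(pupil)) * fps
    pupil_xy <- cbind(ou(n_frames, 5, gaze_sd), ou(n_frames, 5, gaze_sd))
    list(treadmill = tread, pupil = pupil, pupil_d = pupil_d, pupil_xy = pupil_xy)
  })
}

#' Default simulated-session configuration
#'
#' The defaults define the study conditions used throughout: 200 neurons,
#' 20 min of surrogate-natural training stimulus at 30 Hz, two 10 s test
#' clips repeated 8 times, a 16-direction pink-noise battery (2 repeats,
#' 2 s clips) and 150 off/on Gaussian-dot events, all on a 64 x 36 px
#' rendering of the 55.2 x 31.0 cm monitor at 15 cm.
#'
#' @param ... Overrides of the defaults.
#' @return A list of class `session_config`.
#' @export
session_config <- function(...) {
  cfg <- list(
    n_neurons = 200L, fps = 30,
    monitor = monitor_geometry(width_px = 64L, height_px = 36L),
    train_minutes = 20, test_clips = 5L, test_clip_s = 10, test_repeats = 6L,
    battery_directions = 16L, battery_repeats = 2L, battery_clip_s = 2,
    dot_events = 150L,
    noise = "poisson", store_rate = TRUE,
    n_classes = 4L, class_separation = 3
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "session_config")
}

#' Simulate a full recording session
#'
#' Assembles the presentation timeline (training surrogate-natural stimulus,
#' repeated test clips, 16-direction pink-noise battery, Gaussian-dot
#' battery), generates behaviour, simulates responses with the embedded
#' ground-truth population, and returns a [session_bundle()] with the truth
#' attached.
#'
#' @param config A [session_config()].
#' @param seed RNG seed; the population, stimuli, behaviour and noise draw
#'   seeds all derive from it.
#' @param population Optional pre-built `neuron_population` (e.g. to share
#'   neurons' feature basis across sessions).
#' @return A `session_bundle` with `ground_truth$neurons` and (optionally)
#'   `ground_truth$rate`.
#' @export
make_session <- function(config = session_config(), seed = 1L, population = NULL) {
  mon <- config$monitor
  fps <- config$fps
  pop <- if (is.null(population)) {
    make_population(config$n_neurons, seed = seed + 101L,
                    n_classes = config$n_classes,
                    class_separation = config$class_separation)
  } else population

  seg_frames <- list()
  trials <- list()
  clip_counter <- 0L
  add_segment <- function(frames, kind, split, clip_id) {
    seg_frames[[length(seg_frames) + 1L]] <<- frames
    n_prev <- if (length(trials) == 0) 0L else trials[[length(trials)]]$offset_frame
    trials[[length(trials) + 1L]] <<- data.frame(
      trial = length(trials) + 1L, kind = kind, clip_id = clip_id, split = split,
      onset_frame = n_prev + 1L, offset_frame = n_prev + dim(frames)[1])
  }

  # training stimulus
  train_stim <- surrogate_natural(config$train_minutes * 60, seed = seed + 201L,
                                  fps = fps, mon = mon)
  add_segment(train_stim$frames, "surrogate_natural", "train", clip_id = 0L)

  # repeated test clips (unique clip rendered once, repeated in the timeline)
  test_clips <- lapply(seq_len(config$test_clips), function(i) {
    surrogate_natural(config$test_clip_s, seed = seed + 301L + i, fps = fps, mon = mon)
  })
  for (r in seq_len(config$test_repeats)) {
    for (i in seq_len(config$test_clips)) {
      add_segment(test_clips[[i]]$frames, "surrogate_natural", "test", clip_id = i)
    }
  }

  # 16-direction pink-noise battery
  battery <- pink_noise_battery(config$battery_directions, config$battery_repeats,
                                config$battery_clip_s, fps, mon, seed = seed + 401L)
  for (k in seq_along(battery$clips)) {
    add_segment(battery$clips[[k]]$frames, "pink_noise", "battery_pink",
                clip_id = 100L + (k - 1L) %/% battery$repeats)
  }

  # Gaussian-dot battery
  dots <- gaussian_dot_sequence(c("on", "off"), n_events = config$dot_events,
                                seed = seed + 501L, fps = fps, mon = mon)
  add_segment(dots$frames, "dots", "battery_dots", clip_id = 200L)

  frames <- do.call(function(...) {
    parts <- list(...)
    total <- sum(vapply(parts, function(p) dim(p)[1], 0L))
    out <- array(0L, c(total, dim(parts[[1]])[2], dim(parts[[1]])[3]))
    at <- 0L
    for (p in parts) {
      out[at + seq_len(dim(p)[1]), , ] <- p
      at <- at + dim(p)[1]
    }
    out
  }, seg_frames)
  trials <- do.call(rbind, trials)

  T <- dim(frames)[1]
  behavior <- make_behavior(T, fps, seed = seed + 601L)
  rate <- simulate_responses(pop, frames, behavior, mon, noise = "none")
  responses <- if (config$noise == "poisson") {
    with_preserved_seed(seed + 701L, {
      matrix(stats::rpois(length(rate), rate), nrow(rate), ncol(rate))
    })
  } else rate

  gt <- list(neurons = as.data.frame(pop),
             battery = list(directions = battery$directions,
                            repeats = battery$repeats),
             dots_log = dots$log,
             dots_grid = c(dots$grid_rows, dots$grid_cols))
  if (isTRUE(config$store_rate)) gt$rate <- rate
  session_bundle(stimulus = list(frames = frames), behavior = behavior,
                 responses = responses, trials = trials, fps = fps,
                 monitor = mon, ground_truth = gt)
}
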