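# Parametric stimulus generators. All generators are pure functions of their
# arguments and a seed, return frames as integer arrays [T, H, W] in 0..255,
# and log their per-segment parameters. Screen conventions follow the
# geometry module: +x rightward, +y upward, image row 1 at the top. Motion
# direction 0 is rightward, pi/2 upward.

new_stimulus <- function(kind, frames, fps, log = NULL, extra = list()) {
  storage.mode(frames) <- "integer"
  structure(c(list(kind = kind, frames = frames, fps = fps,
                   t = (seq_len(dim(frames)[1]) - 1) / fps, log = log), extra),
            class = "cortex_stimulus")
}

#' @export
print.cortex_stimulus <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cortex_stimulus: %s, %d frames @ %g fps, %d x %d px>\n",
              x$kind, d[1], x$fps, d[2], d[3]))
  invisible(x)
}

# pixel coordinate grids (cm from monitor centre), rows top-down
monitor_px_grid <- function(mon) {
  px <- (seq_len(mon$width_px) - 0.5 - mon$width_px / 2) * (mon$width_cm / mon$width_px)
  py <- (mon$height_px / 2 - (seq_len(mon$height_px) - 0.5)) * (mon$height_cm / mon$height_px)
  list(x = matrix(px, mon$height_px, mon$width_px, byrow = TRUE),
       y = matrix(py, mon$height_px, mon$width_px))
}

clip255 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

#' Directional pink noise
#'
#' Spatiotemporal noise with a 1/f spatial amplitude spectrum whose Fourier
#' energy is restricted to an orientation wedge aligned with the motion axis
#' (producing edges orthogonal to the motion), drifting rigidly along
#' `direction` at `speed_deg_s`. Drift is applied as a Fourier phase ramp, so
#' sub-pixel displacements are exact.
#'
#' @param direction Motion direction in radians (0 = rightward, pi/2 = up).
#' @param duration_s Clip duration in seconds.
#' @param fps Frames per second (default 30).
#' @param mon A [monitor_geometry()] providing the pixel raster and the
#'   degrees-to-pixels conversion at the monitor centre.
#' @param speed_deg_s Drift speed in degrees per second (default 20).
#' @param wedge_half_deg Half-width of the orientation wedge (default 30).
#' @param contrast RMS contrast on the 0-255 scale (default 40).
#' @param seed RNG seed; same seed and parameters give identical frames.
#' @return A `cortex_stimulus` with `log` holding the parameters.
#' @export
directional_pink_noise <- function(direction, duration_s = 2, fps = 30,
                                   mon = monitor_geometry(), speed_deg_s = 20,
                                   wedge_half_deg = 30, contrast = 40, seed = 1L) {
  stopifnot(is.finite(direction))
  h <- mon$height_px; w <- mon$width_px
  n_frames <- floor(duration_s * fps)
  ppd <- pixels_per_degree(mon)
  with_preserved_seed(seed, {
    white <- matrix(stats::rnorm(h * w), h, w)
    F0 <- stats::fft(white)
    fx <- c(0:(floor(w / 2)), -((ceiling(w / 2) - 1):1)) / w
    fy <- c(0:(floor(h / 2)), -((ceiling(h / 2) - 1):1)) / h
    FX <- matrix(fx, h, w, byrow = TRUE)
    FY <- matrix(fy, h, w) # note: +fy corresponds to increasing row index
    fr <- sqrt(FX^2 + FY^2)
    amp <- 1 / (fr + 0.5 / max(h, w))
    # orientation wedge about the motion axis (screen y is up = -row)
    ang <- atan2(-FY, FX)
    dang <- ang - direction
    dang <- atan2(sin(dang), cos(dang))
    dang <- ifelse(abs(dang) > pi / 2, dang - sign(dang) * pi, dang) # axis, mod pi
    hw <- wedge_half_deg * pi / 180
    wedge <- ifelse(abs(dang) <= hw, 0.5 * (1 + cos(pi * dang / hw)), 0)
    amp[1, 1] <- 0
    Fs <- F0 * amp * wedge
    # rigid drift: screen displacement per frame in pixels
    vx <- speed_deg_s / fps * ppd * cos(direction)
    vy_row <- -speed_deg_s / fps * ppd * sin(direction) # +y up -> decreasing row
    base <- Re(stats::fft(Fs, inverse = TRUE)) / (h * w)
    sdv <- stats::sd(as.vector(base))
    scale <- if (sdv > 0) contrast / 255 / sdv else 0
    frames <- array(0L, c(n_frames, h, w))
    for (t in seq_len(n_frames)) {
      shift <- exp(-2i * pi * ((t - 1) * vx * FX + (t - 1) * vy_row * FY))
      img <- Re(stats::fft(Fs * shift, inverse = TRUE)) / (h * w)
      frames[t, , ] <- clip255(127.5 + img * scale * 255)
    }
    new_stimulus("pink_noise", frames, fps,
                 log = data.frame(direction = direction, speed_deg_s = speed_deg_s,
                                  wedge_half_deg = wedge_half_deg,
                                  contrast = contrast, seed = seed))
  })
}

#' Drifting Gabor trial
#'
#' A 10 s trial of 10 drifting Gabor patches (1 s each) with randomly sampled
#' spatial positions, motion directions, phases, spatial and temporal
#' frequencies. The Gaussian envelope s.d. is 16.4 degrees converted to
#' pixels at the monitor centre.
#'
#' @param seed RNG seed.
#' @param fps Frames per second.
#' @param mon A [monitor_geometry()].
#' @param n_segments,segment_s Number and duration of Gabor segments.
#' @param sigma_deg Envelope s.d. in visual degrees (default 16.4).
#' @param sf_range_cpd Log-uniform range of spatial frequency, cycles/degree.
#' @param tf_range_hz Uniform range of temporal frequency, Hz.
#' @return A `cortex_stimulus`; `log` has one row per segment.
#' @export
gabor_trial <- function(seed = 1L, fps = 30, mon = monitor_geometry(),
                        n_segments = 10L, segment_s = 1,
                        sigma_deg = 16.4, sf_range_cpd = c(0.02, 0.2),
                        tf_range_hz = c(1, 8)) {
  h <- mon$height_px; w <- mon$width_px
  grid <- monitor_px_grid(mon)
  deg_per_cm <- angular_resolution(mon, 0)
  sigma_cm <- sigma_deg / deg_per_cm
  seg_frames <- floor(segment_s * fps)
  with_preserved_seed(seed, {
    log <- data.frame(
      segment = seq_len(n_segments),
      onset_frame = (seq_len(n_segments) - 1L) * seg_frames + 1L,
      duration_frames = seg_frames,
      x_cm = stats::runif(n_segments, -mon$width_cm / 2, mon$width_cm / 2),
      y_cm = stats::runif(n_segments, -mon$height_cm / 2, mon$height_cm / 2),
      direction = stats::runif(n_segments, 0, 2 * pi),
      phase = stats::runif(n_segments, 0, 2 * pi),
      sf_cpd = exp(stats::runif(n_segments, log(sf_range_cpd[1]), log(sf_range_cpd[2]))),
      tf_hz = stats::runif(n_segments, tf_range_hz[1], tf_range_hz[2])
    )
    frames <- array(0L, c(n_segments * seg_frames, h, w))
    for (s in seq_len(n_segments)) {
      sf_cpcm <- log$sf_cpd[s] * deg_per_cm # cycles per cm at centre
      dirc <- cos(log$direction[s]); dirs <- sin(log$direction[s])
      xr <- (grid$x - log$x_cm[s]) * dirc + (grid$y - log$y_cm[s]) * dirs
      env <- exp(-((grid$x - log$x_cm[s])^2 + (grid$y - log$y_cm[s])^2) / (2 * sigma_cm^2))
      for (k in seq_len(seg_frames)) {
        tt <- (k - 1) / fps
        carrier <- cos(2 * pi * sf_cpcm * xr - 2 * pi * log$tf_hz[s] * tt + log$phase[s])
        frames[log$onset_frame[s] + k - 1L, , ] <- clip255(127.5 + 127 * env * carrier)
      }
    }
    new_stimulus("gabor", frames, fps, log = log)
  })
}

#' Flashing Gaussian dot sequence
#'
#' 'On' (white) and 'off' (black) Gaussian dots flashed for 300 ms each on a
#' mid-grey background. Dot centres are sampled uniformly from a 17 x 29 grid
#' tiling the monitor; the dot profile is isotropic with s.d. 8 visual
#' degrees converted to pixels at the monitor centre.
#'
#' @param polarity_set Character subset of `c("on", "off")`.
#' @param n_events Number of dot events (>= 1), presented back to back.
#' @param seed RNG seed.
#' @param fps Frames per second.
#' @param mon A [monitor_geometry()].
#' @param flash_s Flash duration (default 0.3 s -> 9 frames at 30 fps).
#' @param sigma_deg Dot s.d. in visual degrees (default 8).
#' @param grid_rows,grid_cols Dot position grid (default 17 x 29).
#' @return A `cortex_stimulus`; `log` has one row per event (grid_row,
#'   grid_col are 1-based; row 1 = top).
#' @export
gaussian_dot_sequence <- function(polarity_set = c("on", "off"), n_events = 100L,
                                  seed = 1L, fps = 30, mon = monitor_geometry(),
                                  flash_s = 0.3, sigma_deg = 8,
                                  grid_rows = 17L, grid_cols = 29L) {
  stopifnot(n_events >= 1, all(polarity_set %in% c("on", "off")))
  h <- mon$height_px; w <- mon$width_px
  ev_frames <- round(flash_s * fps)
  grid <- monitor_px_grid(mon)
  deg_per_cm <- angular_resolution(mon, 0)
  sigma_cm <- sigma_deg / deg_per_cm
  # grid cell centres in cm (row 1 = top)
  row_y <- (grid_rows / 2 - (seq_len(grid_rows) - 0.5)) / grid_rows * mon$height_cm
  col_x <- ((seq_len(grid_cols) - 0.5) - grid_cols / 2) / grid_cols * mon$width_cm
  with_preserved_seed(seed, {
    log <- data.frame(
      event = seq_len(n_events),
      grid_row = sample.int(grid_rows, n_events, replace = TRUE),
      grid_col = sample.int(grid_cols, n_events, replace = TRUE),
      polarity = sample(polarity_set, n_events, replace = TRUE),
      onset_frame = (seq_len(n_events) - 1L) * ev_frames + 1L,
      duration_frames = ev_frames
    )
    frames <- array(127L, c(n_events * ev_frames, h, w))
    for (e in seq_len(n_events)) {
      cx <- col_x[log$grid_col[e]]; cy <- row_y[log$grid_row[e]]
      prof <- exp(-((grid$x - cx)^2 + (grid$y - cy)^2) / (2 * sigma_cm^2))
      pol <- if (log$polarity[e] == "on") 1 else -1
      img <- clip255(127.5 + pol * 127.5 * prof)
      for (k in seq_len(ev_frames)) frames[log$onset_frame[e] + k - 1L, , ] <- img
    }
    new_stimulus("dots", frames, fps, log = log,
                 extra = list(grid_rows = grid_rows, grid_cols = grid_cols))
  })
}

#' Random dot kinematogram
#'
#' A 10 s trial of 5 optical-flow patterns (2 s each), sampled from
#' translation (up/down/left/right), radial (in/out) and rotation
#' (clockwise/anticlockwise) at 50% or 100% coherence. A coherent fraction of
#' dots follows the flow field; the rest move in random fixed directions.
#' Dots are white discs of radius 2.6 degrees at the monitor centre.
#'
#' @param seed RNG seed.
#' @param fps Frames per second.
#' @param mon A [monitor_geometry()].
#' @param n_segments,segment_s Number and duration of flow segments.
#' @param n_dots Dots per segment (default 30).
#' @param speed_deg_s Translation / flow speed in degrees per second.
#' @param radius_deg Dot radius in visual degrees (default 2.6).
#' @return A `cortex_stimulus`; `log` has one row per segment and
#'   `trajectories` holds per-segment dot tracks (`n_dots x 2 x frames`, cm).
#' @export
kinematogram <- function(seed = 1L, fps = 30, mon = monitor_geometry(),
                         n_segments = 5L, segment_s = 2, n_dots = 30L,
                         speed_deg_s = 25, radius_deg = 2.6) {
  h <- mon$height_px; w <- mon$width_px
  grid <- monitor_px_grid(mon)
  deg_per_cm <- angular_resolution(mon, 0)
  radius_cm <- radius_deg / deg_per_cm
  speed_cm <- speed_deg_s / deg_per_cm / fps # cm per frame
  seg_frames <- floor(segment_s * fps)
  patterns <- c("trans_up", "trans_down", "trans_left", "trans_right",
                "radial_in", "radial_out", "rot_cw", "rot_ccw")
  flow_at <- function(pattern, pos) {
    switch(pattern,
      trans_up = cbind(0, rep(speed_cm, nrow(pos))),
      trans_down = cbind(0, rep(-speed_cm, nrow(pos))),
      trans_left = cbind(rep(-speed_cm, nrow(pos)), 0),
      trans_right = cbind(rep(speed_cm, nrow(pos)), 0),
      radial_out = {
        r <- sqrt(rowSums(pos^2)) + 1e-6
        pos / r * speed_cm
      },
      radial_in = {
        r <- sqrt(rowSums(pos^2)) + 1e-6
        -pos / r * speed_cm
      },
      rot_ccw = {
        r <- sqrt(rowSums(pos^2)) + 1e-6
        cbind(-pos[, 2], pos[, 1]) / r * speed_cm
      },
      rot_cw = {
        r <- sqrt(rowSums(pos^2)) + 1e-6
        cbind(pos[, 2], -pos[, 1]) / r * speed_cm
      })
  }
  half_w <- mon$width_cm / 2; half_h <- mon$height_cm / 2
  with_preserved_seed(seed, {
    log <- data.frame(
      segment = seq_len(n_segments),
      onset_frame = (seq_len(n_segments) - 1L) * seg_frames + 1L,
      duration_frames = seg_frames,
      pattern = sample(patterns, n_segments, replace = TRUE),
      coherence = sample(c(0.5, 1), n_segments, replace = TRUE)
    )
    frames <- array(0L, c(n_segments * seg_frames, h, w))
    trajectories <- vector("list", n_segments)
    for (s in seq_len(n_segments)) {
      pos <- cbind(stats::runif(n_dots, -half_w, half_w),
                   stats::runif(n_dots, -half_h, half_h))
      coh <- stats::runif(n_dots) < log$coherence[s]
      rnd_dir <- stats::runif(n_dots, 0, 2 * pi)
      tr <- array(NA_real_, c(n_dots, 2, seg_frames))
      for (k in seq_len(seg_frames)) {
        tr[, , k] <- pos
        img <- matrix(0, h, w)
        for (d in seq_len(n_dots)) {
          disc <- (grid$x - pos[d, 1])^2 + (grid$y - pos[d, 2])^2 <= radius_cm^2
          img[disc] <- 1
        }
        frames[log$onset_frame[s] + k - 1L, , ] <- clip255(img * 255)
        vel <- flow_at(log$pattern[s], pos)
        vel[!coh, ] <- speed_cm * cbind(cos(rnd_dir[!coh]), sin(rnd_dir[!coh]))
        pos <- pos + vel
        # wrap around the screen
        pos[, 1] <- ((pos[, 1] + half_w) %% mon$width_cm) - half_w
        pos[, 2] <- ((pos[, 2] + half_h) %% mon$height_cm) - half_h
      }
      trajectories[[s]] <- list(track = tr, coherent = coh)
    }
    new_stimulus("kinematogram", frames, fps, log = log,
                 extra = list(trajectories = trajectories))
  })
}

#' Procedural surrogate for natural training videos
#'
#' A naturalistic training-stimulus stand-in built from the parametric
#' generators: a sequence of 2 s segments, each drawn as directional pink
#' noise with a random direction and speed (default 70%), a drifting Gabor
#' (15%) or a burst of flashing Gaussian dots (15%). This provides broadband
#' spatial structure, coherent motion in all directions and localized
#' luminance events, which is what the encoder needs to learn direction- and
#' position-selective responses; it does not emulate natural image statistics
#' beyond the 1/f spectrum.
#'
#' @param duration_s Total duration (rounded down to whole segments).
#' @param seed RNG seed.
#' @param fps Frames per second.
#' @param mon A [monitor_geometry()].
#' @param segment_s Segment duration (default 2 s).
#' @param mix Probabilities for c(pink_noise, gabor, dots) segments.
#' @return A `cortex_stimulus`; `log` has one row per segment.
#' @export
surrogate_natural <- function(duration_s = 60, seed = 1L, fps = 30,
                              mon = monitor_geometry(), segment_s = 2,
                              mix = c(0.7, 0.15, 0.15)) {
  n_seg <- max(1L, floor(duration_s / segment_s))
  seg_frames <- floor(segment_s * fps)
  h <- mon$height_px; w <- mon$width_px
  with_preserved_seed(seed, {
    kinds <- sample(c("pink_noise", "gabor", "dots"), n_seg, replace = TRUE, prob = mix)
    seeds <- sample.int(.Machine$integer.max, n_seg)
    dirs <- stats::runif(n_seg, 0, 2 * pi)
    speeds <- stats::runif(n_seg, 10, 35)
    frames <- array(127L, c(n_seg * seg_frames, h, w))
    log <- data.frame(segment = seq_len(n_seg), kind = kinds,
                      onset_frame = (seq_len(n_seg) - 1L) * seg_frames + 1L,
                      duration_frames = seg_frames,
                      direction = dirs, speed_deg_s = speeds, seed = seeds)
    for (s in seq_len(n_seg)) {
      sub <- switch(kinds[s],
        pink_noise = directional_pink_noise(dirs[s], segment_s, fps, mon,
                                            speed_deg_s = speeds[s], seed = seeds[s]),
        gabor = gabor_trial(seed = seeds[s], fps = fps, mon = mon,
                            n_segments = max(1L, round(segment_s)), segment_s = 1),
        dots = gaussian_dot_sequence(n_events = max(1L, floor(segment_s / 0.3)),
                                     seed = seeds[s], fps = fps, mon = mon))
      nf <- min(seg_frames, dim(sub$frames)[1])
      frames[log$onset_frame[s] + seq_len(nf) - 1L, , ] <- sub$frames[seq_len(nf), , ]
    }
    new_stimulus("surrogate_natural", frames, fps, log = log)
  })
}

#' Battery of directional pink-noise clips
#'
#' Convenience wrapper: `n_directions` angles uniform on `[0, 2pi)`, each
#' rendered `repeats` times with distinct seeds.
#'
#' @param n_directions Number of directions (default 16).
#' @param repeats Clips per direction.
#' @param duration_s Duration of each clip.
#' @param seed Base seed.
#' @inheritParams directional_pink_noise
#' @return List with `directions` and a list `clips` (one `cortex_stimulus`
#'   per direction x repeat, in direction-major order).
#' @export
pink_noise_battery <- function(n_directions = 16L, repeats = 2L, duration_s = 2,
                               fps = 30, mon = monitor_geometry(), seed = 1L,
                               speed_deg_s = 20) {
  directions <- 2 * pi * (seq_len(n_directions) - 1L) / n_directions
  clips <- list()
  idx <- 1L
  for (i in seq_len(n_directions)) {
    for (r in seq_len(repeats)) {
      clips[[idx]] <- directional_pink_noise(directions[i], duration_s, fps, mon,
                                             speed_deg_s = speed_deg_s,
                                             seed = seed + 1000L * i + r)
      idx <- idx + 1L
    }
  }
  list(directions = directions, repeats = repeats, clips = clips)
}
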