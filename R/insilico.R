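# In-silico experiments: present parametric stimulus batteries to a trained
# encoder (instead of the animal) and estimate tuning from the predicted
# responses, mirroring the in vivo estimation pipeline.

#' In-silico orientation/direction tuning
#'
#' Presents a 16-direction pink-noise battery to the model under resting
#' behaviour, averages predicted responses into per-direction tuning curves
#' and estimates OSI/DSI and the preferred direction via the von Mises
#' mixture fit.
#'
#' @param model A trained `encoder_model`.
#' @param n_directions,repeats,duration_s Battery layout (default 16 x 2 x 2 s).
#' @param seed Battery stimulus seed.
#' @param warmup_frames Frames discarded at each clip onset.
#' @param chunk Frames predicted per forward call.
#' @return List with `table` (per neuron: osi, dsi, pref_direction,
#'   pref_orientation, flag), `curves`, `angles`.
#' @export
insilico_direction_tuning <- function(model, n_directions = 16L, repeats = 2L,
                                      duration_s = 2, seed = 1L,
                                      warmup_frames = 5L, chunk = 120L) {
  batt <- pink_noise_battery(n_directions, repeats, duration_s, fps = 30,
                             mon = model$mon, seed = seed)
  resp <- NULL
  for (cl in batt$clips) {
    resp <- rbind(resp, predict_in_chunks(model, cl$frames, chunk))
  }
  tc <- tuning_curves_from_battery(resp, batt, warmup_frames)
  N <- model$n_neurons
  rows <- lapply(seq_len(N), function(n) {
    idx <- osi_dsi(tc$angles, tc$curves[, n])
    fit <- fit_von_mises(tc$angles, tc$curves[, n])
    data.frame(neuron = n, osi = idx$osi, dsi = idx$dsi,
               pref_direction = fit$mu, pref_orientation = fit$pref_orientation,
               kappa = fit$kappa, flag = fit$flag)
  })
  list(table = do.call(rbind, rows), curves = tc$curves, angles = tc$angles)
}

#' In-silico spatial tuning from flashing Gaussian dots
#'
#' Presents an 'off'-dot sequence, computes each neuron's response-weighted
#' stimulus average (STA), its moments/SSI in dot-grid units and the 2D
#' Gaussian fit of the preferred location.
#'
#' @param model A trained `encoder_model`.
#' @param n_events Number of dot events (default 150).
#' @param seed Dot stimulus seed.
#' @param max_lag Response lags tried; the lag maximizing summed STA
#'   contrast across neurons is used for all neurons.
#' @param chunk Frames predicted per forward call.
#' @return List with `table` (per neuron: ssi, rf_row, rf_col, mu_row,
#'   mu_col in dot-grid cell units, flag), `stas` (pixel-unit maps), `lag`,
#'   and the stimulus `log`.
#' @export
insilico_spatial_tuning <- function(model, n_events = 150L, seed = 1L,
                                    max_lag = 5L, chunk = 120L) {
  stim <- gaussian_dot_sequence("off", n_events = n_events, seed = seed,
                                mon = model$mon)
  resp <- predict_in_chunks(model, stim$frames, chunk)
  sta_spatial_table(stim, resp, max_lag = max_lag)
}

# shared STA + moments + Gaussian fit pipeline for a dot stimulus and any
# response matrix (predicted or recorded)
sta_spatial_table <- function(stim, resp, max_lag = 5L) {
  T <- dim(stim$frames)[1]
  h <- dim(stim$frames)[2]; w <- dim(stim$frames)[3]
  dev <- abs(matrix(stim$frames, T, h * w) - 127.5)
  N <- ncol(resp)
  r <- pmax(resp, 0)
  # common lag: maximize total STA contrast over neurons
  best <- NULL
  for (L in 0:max_lag) {
    idx <- seq_len(T - L)
    wts <- r[idx + L, , drop = FALSE]
    tot <- colSums(wts)
    sta <- crossprod(dev[idx, , drop = FALSE], wts)
    sta <- sweep(sta, 2, pmax(tot, 1e-12), "/")
    contrast <- sum(apply(sta, 2, stats::var))
    if (is.null(best) || contrast > best$contrast) {
      best <- list(sta = sta, lag = L, contrast = contrast)
    }
  }
  cell <- c(h / stim$grid_rows, w / stim$grid_cols) # pixels per grid cell
  rows <- lapply(seq_len(N), function(n) {
    m <- matrix(best$sta[, n], h, w)
    mom <- sta_moments_ssi(m, cell_size = 1 / cell) # coordinates in cells
    fit <- fit_spatial_gaussian(m)
    mu_cells <- if (is.null(fit$mu)) c(NA_real_, NA_real_) else fit$mu / cell
    data.frame(neuron = n,
               ssi = if (mom$defined) mom$ssi else NA_real_,
               rf_row = if (mom$defined) mom$centroid[1] else NA_real_,
               rf_col = if (mom$defined) mom$centroid[2] else NA_real_,
               mu_row = mu_cells[1], mu_col = mu_cells[2],
               flag = fit$flag)
  })
  list(table = do.call(rbind, rows),
       stas = best$sta, lag = best$lag, log = stim$log,
       grid = c(stim$grid_rows, stim$grid_cols))
}

predict_in_chunks <- function(model, frames, chunk = 120L) {
  T <- dim(frames)[1]
  out <- NULL
  for (c0 in seq(1L, T, by = chunk)) {
    idx <- c0:min(T, c0 + chunk - 1L)
    out <- rbind(out, predict_responses(model, frames[idx, , , drop = FALSE]))
  }
  out
}

#' Readout feature-weight barcodes of a trained model
#'
#' Concatenates each neuron's readout feature weights across heads into one
#' barcode vector.
#'
#' @param model A trained `encoder_model`.
#' @return `N x (C * heads)` matrix.
#' @export
readout_barcodes <- function(model) {
  do.call(cbind, lapply(model$params$heads, function(h) h$readout$w))
}
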