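# Parametric tuning estimation: orientation/direction selectivity indices,
# von Mises mixture fits, spike-triggered averages, spatial selectivity and
# 2D Gaussian receptive-field fits. All estimators work on any response
# source (recorded, simulated or model-predicted), enabling in vivo vs in
# silico comparisons.

#' Orientation and direction selectivity indices
#'
#' `OSI = |sum_theta r_theta e^(i 2 theta)| / sum_theta r_theta` and
#' `DSI = |sum_theta r_theta e^(i theta)| / sum_theta r_theta`: the
#' normalized magnitudes of the second and first circular Fourier components
#' of the tuning curve. Negative mean responses (possible after detrending)
#' are clamped to zero, as the indices assume nonnegative rates.
#'
#' @param angles Stimulus directions in radians (typically 16 uniform on
#'   `[0, 2pi)`).
#' @param responses Mean response per angle.
#' @return List with `osi`, `dsi` (both in `[0, 1]`) and `defined` (FALSE for
#'   an all-zero curve).
#' @export
osi_dsi <- function(angles, responses) {
  stopifnot(length(angles) == length(responses))
  r <- pmax(responses, 0)
  tot <- sum(r)
  if (tot <= 0) return(list(osi = NA_real_, dsi = NA_real_, defined = FALSE))
  osi <- Mod(sum(r * exp(2i * angles))) / tot
  dsi <- Mod(sum(r * exp(1i * angles))) / tot
  list(osi = osi, dsi = dsi, defined = TRUE)
}

von_mises_mixture <- function(theta, mu, kappa, alpha, beta, gamma) {
  alpha * exp(kappa * cos(theta - mu)) + beta * exp(kappa * cos(theta - mu + pi)) + gamma
}

#' Fit a two-lobe von Mises mixture to a direction tuning curve
#'
#' Least-squares fit of
#' `f(theta) = alpha e^(kappa cos(theta - mu)) + beta e^(kappa cos(theta - mu + pi)) + gamma`
#' by multi-start Levenberg-Marquardt (8 equispaced `mu` starts x 2 `kappa`
#' starts; bounds `kappa` in `[0, 20]`, `alpha, beta, gamma >= 0`). The fit
#' with the smallest residual wins, ties going to the smaller `kappa`;
#' `alpha >= beta` is enforced by swapping lobes (`mu -> mu + pi`) so `mu`
#' always marks the dominant direction. The preferred orientation is the
#' angle orthogonal to `mu`: `(mu + pi/2) mod pi`.
#'
#' @param angles Stimulus directions (radians), at least 5 distinct.
#' @param responses Mean response per angle.
#' @return An object of class `von_mises_fit`: `mu`, `kappa`, `alpha`,
#'   `beta`, `gamma`, `pref_orientation`, `residual`, `flag`
#'   (`"ok"`/`"low_modulation"`/`"failed"`).
#' @export
fit_von_mises <- function(angles, responses) {
  if (length(unique(round(angles, 9))) < 5) {
    stop("need at least 5 distinct angles", call. = FALSE)
  }
  r <- pmax(responses, 0)
  scale <- max(r)
  if (scale <= 0) {
    return(structure(list(mu = NA_real_, kappa = 0, alpha = 0, beta = 0,
                          gamma = 0, pref_orientation = NA_real_,
                          residual = 0, flag = "low_modulation"),
                     class = "von_mises_fit"))
  }
  resid_fun <- function(p) {
    von_mises_mixture(angles, p[1], p[2], p[3], p[4], p[5]) - r
  }
  best <- NULL
  mu_starts <- 2 * pi * (0:7) / 8
  for (mu0 in mu_starts) for (k0 in c(1, 5)) {
    p0 <- c(mu0, k0, scale / exp(k0), scale / (2 * exp(k0)), max(min(r), 1e-6))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fun,
                         lower = c(-Inf, 0, 0, 0, 0),
                         upper = c(Inf, 20, Inf, Inf, Inf),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(resid_fun(fit$par)^2)
    if (is.null(best) || ss < best$ss - 1e-12 ||
        (abs(ss - best$ss) <= 1e-12 && fit$par[2] < best$par[2])) {
      best <- list(par = fit$par, ss = ss)
    }
  }
  if (is.null(best)) {
    return(structure(list(mu = NA_real_, kappa = NA_real_, alpha = NA_real_,
                          beta = NA_real_, gamma = NA_real_,
                          pref_orientation = NA_real_, residual = NA_real_,
                          flag = "failed"), class = "von_mises_fit"))
  }
  p <- best$par
  if (p[4] > p[3]) { # swap lobes so alpha marks the dominant direction
    p[1] <- p[1] + pi
    p[3:4] <- p[4:3]
  }
  mu <- p[1] %% (2 * pi)
  mod_depth <- (p[3] + p[4]) * (exp(p[2]) - exp(-p[2]))
  flag <- if (mod_depth < 1e-3 * scale) "low_modulation" else "ok"
  structure(list(mu = mu, kappa = p[2], alpha = p[3], beta = p[4], gamma = p[5],
                 pref_orientation = (mu + pi / 2) %% pi,
                 residual = best$ss, flag = flag),
            class = "von_mises_fit")
}

#' Angular differences between two preferred directions
#'
#' `DeltaDirection = arccos(cos(mu_a - mu_b))` in `[0, pi]` and
#' `DeltaOrientation = arccos(cos(2 mu_a - 2 mu_b)) / 2` in `[0, pi/2]`.
#' Accepts raw angles or `von_mises_fit` objects; symmetric in its arguments.
#'
#' @param fit_a,fit_b Angles in radians or `von_mises_fit` objects.
#' @return List with `delta_direction` and `delta_orientation` (radians).
#' @export
angular_deltas <- function(fit_a, fit_b) {
  mu_a <- if (inherits(fit_a, "von_mises_fit")) fit_a$mu else fit_a
  mu_b <- if (inherits(fit_b, "von_mises_fit")) fit_b$mu else fit_b
  cl <- function(x) pmin(pmax(x, -1), 1)
  list(delta_direction = acos(cl(cos(mu_a - mu_b))),
       delta_orientation = acos(cl(cos(2 * mu_a - 2 * mu_b))) / 2)
}

#' Response-weighted stimulus average (STA)
#'
#' `sta[x] = sum_t |s[x, t] - s0| r[t + lag] / sum_t r[t + lag]`: the
#' average absolute stimulus deviation from the grey reference, weighted by
#' the (nonnegative) response. With `lag = "auto"` the integer lag in
#' `0..max_lag` frames maximizing STA contrast (variance) is chosen, which
#' absorbs response latency.
#'
#' @param frames Stimulus array `[T, H, W]` (0-255 or 0-1 scale).
#' @param responses Length-T response trace aligned to frames.
#' @param s0 Grey reference on the same scale as `frames` (default 127.5).
#' @param lag Integer response lag in frames, or `"auto"`.
#' @param max_lag Largest lag tried under `"auto"` (default 5).
#' @param frame_mask Optional logical length-T mask restricting which frames
#'   enter the average (e.g. only 'off'-dot frames).
#' @return An object of class `sta_map`: `map` (`H x W`), `lag`, `defined`.
#' @export
compute_sta <- function(frames, responses, s0 = 127.5, lag = "auto",
                        max_lag = 5L, frame_mask = NULL) {
  T <- dim(frames)[1]
  stopifnot(length(responses) == T)
  r <- pmax(responses, 0)
  if (is.null(frame_mask)) frame_mask <- rep(TRUE, T)
  dev <- abs(matrix(frames, T, prod(dim(frames)[2:3])) - s0)
  sta_at <- function(L) {
    idx <- which(frame_mask & seq_len(T) + L <= T)
    wt <- r[idx + L]
    tot <- sum(wt)
    if (tot <= 0) return(NULL)
    matrix(colSums(dev[idx, , drop = FALSE] * wt) / tot,
           dim(frames)[2], dim(frames)[3])
  }
  lags <- if (identical(lag, "auto")) 0:max_lag else as.integer(lag)
  best <- NULL
  for (L in lags) {
    m <- sta_at(L)
    if (is.null(m)) next
    contrast <- var_pop(as.vector(m))
    if (is.null(best) || contrast > best$contrast) {
      best <- list(map = m, lag = L, contrast = contrast)
    }
  }
  if (is.null(best)) {
    return(structure(list(map = NULL, lag = NA_integer_, defined = FALSE),
                     class = "sta_map"))
  }
  structure(list(map = best$map, lag = best$lag, defined = TRUE),
            class = "sta_map")
}

#' Spatial moments and selectivity index of an STA
#'
#' Treating the STA as a mass distribution over pixel coordinates
#' `x = (row, col)`: `z = sum sta`, centroid `xbar = sum sta x / z`,
#' `Sigma_STA = sum sta (x - xbar)(x - xbar)^T / z`, and
#' `SSI = -log |Sigma_STA|`. Coordinates may be rescaled (e.g. to dot-grid
#' cells) via `cell_size`; a single-pixel mass gives `SSI = +Inf` (flagged).
#'
#' @param sta An `sta_map` or a plain nonnegative matrix.
#' @param cell_size Length-2 factor `(rows, cols)` converting pixel indices
#'   to the desired coordinate units (default `c(1, 1)` = pixels).
#' @return List with `centroid` (row, col), `sigma` (2 x 2), `ssi`,
#'   `defined`, `degenerate`.
#' @export
sta_moments_ssi <- function(sta, cell_size = c(1, 1)) {
  m <- if (inherits(sta, "sta_map")) sta$map else sta
  if (is.null(m)) return(list(centroid = NULL, sigma = NULL, ssi = NA_real_,
                              defined = FALSE, degenerate = FALSE))
  z <- sum(m)
  if (z <= 0) return(list(centroid = NULL, sigma = NULL, ssi = NA_real_,
                          defined = FALSE, degenerate = FALSE))
  h <- nrow(m); w <- ncol(m)
  rows <- matrix(seq_len(h) * cell_size[1], h, w)
  cols <- matrix(rep(seq_len(w) * cell_size[2], each = h), h, w)
  cr <- sum(m * rows) / z
  cc <- sum(m * cols) / z
  s11 <- sum(m * (rows - cr)^2) / z
  s22 <- sum(m * (cols - cc)^2) / z
  s12 <- sum(m * (rows - cr) * (cols - cc)) / z
  sigma <- matrix(c(s11, s12, s12, s22), 2, 2)
  detS <- s11 * s22 - s12^2
  if (detS <= 0) {
    return(list(centroid = c(row = cr, col = cc), sigma = sigma, ssi = Inf,
                defined = TRUE, degenerate = TRUE))
  }
  list(centroid = c(row = cr, col = cc), sigma = sigma, ssi = -log(detS),
       defined = TRUE, degenerate = FALSE)
}

#' Fit a 2D Gaussian plus baseline to an STA
#'
#' Least-squares fit of
#' `f(x) = alpha exp(-(x - mu)^T Sigma^(-1) (x - mu) / 2) + gamma` over pixel
#' coordinates, by Levenberg-Marquardt. `mu` is initialized at the STA
#' argmax and `Sigma` from the STA moments (parameterized by its Cholesky
#' factor so it stays positive definite).
#'
#' @param sta An `sta_map` or plain matrix.
#' @return An object of class `spatial_fit`: `mu` (row, col), `sigma`
#'   (2 x 2 PSD), `alpha`, `gamma`, `residual`, `flag`.
#' @export
fit_spatial_gaussian <- function(sta) {
  m <- if (inherits(sta, "sta_map")) sta$map else sta
  if (is.null(m)) {
    return(structure(list(mu = NULL, sigma = NULL, alpha = NA_real_,
                          gamma = NA_real_, residual = NA_real_, flag = "failed"),
                     class = "spatial_fit"))
  }
  h <- nrow(m); w <- ncol(m)
  rng <- max(m) - min(m)
  mom <- sta_moments_ssi(m)
  if (rng <= 1e-12 || !mom$defined) {
    return(structure(list(mu = NULL, sigma = NULL, alpha = 0, gamma = mean(m),
                          residual = 0, flag = "low_amplitude"),
                     class = "spatial_fit"))
  }
  pk <- which(m == max(m), arr.ind = TRUE)[1, ]
  # initial covariance from the moments of the baseline-subtracted map (a
  # flat offset otherwise inflates the spread towards the whole-map variance)
  mom0 <- sta_moments_ssi(m - min(m))
  S0 <- (if (mom0$defined && !mom0$degenerate) mom0$sigma else mom$sigma) + diag(2) * 0.25
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(rep(seq_len(w), each = h), h, w)
  resid_fun <- function(p) {
    mu <- p[1:2]
    L <- matrix(c(p[3], p[4], 0, p[5]), 2, 2)
    S <- L %*% t(L) + diag(2) * 1e-9
    Si <- solve(S)
    dr <- rows - mu[1]; dc <- cols - mu[2]
    q <- Si[1, 1] * dr^2 + 2 * Si[1, 2] * dr * dc + Si[2, 2] * dc^2
    as.vector(p[6] * exp(-q / 2) + p[7] - m)
  }
  # multi-start: moment-based and compact isotropic initializations
  starts <- list()
  L0 <- t(chol(S0))
  starts[[1]] <- c(pk[1], pk[2], L0[1, 1], L0[2, 1], L0[2, 2], rng, min(m))
  starts[[2]] <- c(pk[1], pk[2], 2, 0, 2, rng, min(m))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fun,
                         lower = c(-Inf, -Inf, 1e-4, -Inf, 1e-4, 0, 0),
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(resid_fun(fit$par)^2)
    if (is.null(best) || ss < best$ss) best <- list(par = fit$par, ss = ss)
  }
  if (is.null(best)) {
    return(structure(list(mu = NULL, sigma = NULL, alpha = NA_real_,
                          gamma = NA_real_, residual = NA_real_, flag = "failed"),
                     class = "spatial_fit"))
  }
  p <- unname(best$par)
  L <- matrix(c(p[3], p[4], 0, p[5]), 2, 2)
  flag <- if (p[6] < 1e-3 * rng) "low_amplitude" else "ok"
  structure(list(mu = c(row = p[1], col = p[2]), sigma = L %*% t(L),
                 alpha = p[6], gamma = p[7],
                 residual = sum(resid_fun(p)^2), flag = flag),
            class = "spatial_fit")
}

#' Euclidean distance between two preferred spatial locations
#' @param fit_a,fit_b `spatial_fit` objects or length-2 position vectors.
#' @return Scalar distance in the fits' coordinate units.
#' @export
delta_location <- function(fit_a, fit_b) {
  a <- if (inherits(fit_a, "spatial_fit")) fit_a$mu else fit_a
  b <- if (inherits(fit_b, "spatial_fit")) fit_b$mu else fit_b
  sqrt(sum((a - b)^2))
}

#' Direction tuning curve from battery responses
#'
#' Averages responses over repeats and over the frames of each directional
#' clip (discarding `warmup_frames` at each clip onset) to produce the
#' 16-angle mean tuning curve used by [osi_dsi()] and [fit_von_mises()].
#'
#' @param responses `T x N` response matrix over the concatenated battery.
#' @param battery The battery description from [pink_noise_battery()].
#' @param warmup_frames Frames dropped at each clip onset (default 5).
#' @return List with `angles` and `curves` (`n_directions x N`).
#' @export
tuning_curves_from_battery <- function(responses, battery, warmup_frames = 5L) {
  n_dir <- length(battery$directions)
  reps <- battery$repeats
  clip_len <- dim(battery$clips[[1]]$frames)[1]
  N <- ncol(responses)
  curves <- matrix(0, n_dir, N)
  at <- 0L
  for (i in seq_len(n_dir)) {
    acc <- numeric(N)
    for (r in seq_len(reps)) {
      rows <- at + (warmup_frames + 1L):clip_len
      acc <- acc + colMeans(responses[rows, , drop = FALSE])
      at <- at + clip_len
    }
    curves[i, ] <- acc / reps
  }
  list(angles = battery$directions, curves = curves)
}
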