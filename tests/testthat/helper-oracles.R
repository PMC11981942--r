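# Shared fixtures and independent brute-force oracles used across tests.

tiny_monitor <- function() monitor_geometry(width_px = 32L, height_px = 18L)

# brute-force CC metrics straight from the printed formulas, population
# variance convention, plain loops
oracle_cc <- function(pred, trials) {
  N <- nrow(trials); T <- ncol(trials)
  ybar <- numeric(T)
  for (t in seq_len(T)) ybar[t] <- mean(trials[, t])
  vp <- function(x) {
    m <- sum(x) / length(x)
    s <- 0
    for (xi in x) s <- s + (xi - m)^2
    s / length(x)
  }
  cv <- function(x, y) {
    mx <- sum(x) / length(x); my <- sum(y) / length(y)
    s <- 0
    for (i in seq_along(x)) s <- s + (x[i] - mx) * (y[i] - my)
    s / length(x)
  }
  cc_abs <- cv(pred, ybar) / sqrt(vp(pred) * vp(ybar))
  mean_var <- 0
  for (i in seq_len(N)) mean_var <- mean_var + vp(trials[i, ])
  mean_var <- mean_var / N
  cc_max <- sqrt((N * vp(ybar) - mean_var) / ((N - 1) * vp(ybar)))
  list(cc_abs = cc_abs, cc_max = cc_max, cc_norm = cc_abs / cc_max)
}

# brute-force selectivity indices via explicit complex sums
oracle_osi_dsi <- function(angles, r) {
  r <- pmax(r, 0)
  s1 <- 0 + 0i; s2 <- 0 + 0i; tot <- 0
  for (i in seq_along(angles)) {
    s1 <- s1 + r[i] * exp(1i * angles[i])
    s2 <- s2 + r[i] * exp(2i * angles[i])
    tot <- tot + r[i]
  }
  list(osi = Mod(s2) / tot, dsi = Mod(s1) / tot)
}

# brute-force STA moments over explicit pixel loops
oracle_sta_moments <- function(m) {
  h <- nrow(m); w <- ncol(m)
  z <- 0; cr <- 0; cc <- 0
  for (i in seq_len(h)) for (j in seq_len(w)) {
    z <- z + m[i, j]; cr <- cr + m[i, j] * i; cc <- cc + m[i, j] * j
  }
  cr <- cr / z; cc <- cc / z
  s11 <- 0; s22 <- 0; s12 <- 0
  for (i in seq_len(h)) for (j in seq_len(w)) {
    s11 <- s11 + m[i, j] * (i - cr)^2
    s22 <- s22 + m[i, j] * (j - cc)^2
    s12 <- s12 + m[i, j] * (i - cr) * (j - cc)
  }
  sigma <- matrix(c(s11, s12, s12, s22) / z, 2, 2)
  list(centroid = c(cr, cc), sigma = sigma, ssi = -log(det(sigma)))
}

oracle_poisson <- function(r, y) {
  s <- 0
  for (i in seq_along(r)) s <- s + r[i] - if (y[i] > 0) y[i] * log(r[i]) else 0
  s
}

# phase-correlation shift between two frames (integer-pixel resolution)
phase_corr_shift <- function(a, b) {
  A <- stats::fft(a); B <- stats::fft(b)
  R <- B * Conj(A)
  R <- R / (Mod(R) + 1e-12)
  r <- Re(stats::fft(R, inverse = TRUE))
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  h <- nrow(a); w <- ncol(a)
  dy <- unname(pk[1]) - 1
  if (dy > h / 2) dy <- dy - h
  dx <- unname(pk[2]) - 1
  if (dx > w / 2) dx <- dx - w
  c(dx = dx, dy = dy)
}

wrap_angle <- function(x) atan2(sin(x), cos(x))

zeroed <- function(params) map_params(params, function(x) { x[] <- 0; x })

# finite-difference gradient of f at x (elementwise), f maps array -> scalar
fd_grad <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps
    x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

tiny_cfg <- function(...) {
  desk_encoder_config(grid_height = 17L, grid_width = 25L,
                      cell_channels = 4L, ...)
}

tiny_model <- function(n = 6, cfg = tiny_cfg(), seed = 1) {
  encoder_init(cfg, n_neurons = n, mon = tiny_monitor(), seed = seed)
}

rand_inputs <- function(T, seed = 2, mon = tiny_monitor()) {
  set.seed(seed)
  list(frames = array(sample(0:255, T * mon$height_px * mon$width_px, TRUE),
                      c(T, mon$height_px, mon$width_px)),
       behavior = list(treadmill = runif(T), pupil = runif(T), pupil_d = rnorm(T)),
       pupil_xy = matrix(rnorm(2 * T) * 0.5, T, 2))
}

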