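angles16 <- 2 * pi * (0:15) / 16

test_that("selectivity indices match their discrete Fourier definitions", {
  # flat curve: phasors cancel
  flat <- osi_dsi(angles16, rep(2, 16))
  expect_equal(flat$osi, 0, tolerance = 1e-12)
  expect_equal(flat$dsi, 0, tolerance = 1e-12)
  # single-harmonic curves: index exactly 1/2
  d1 <- osi_dsi(angles16, 1 + cos(angles16 - 0.7))
  expect_equal(d1$dsi, 0.5, tolerance = 1e-12)
  expect_equal(d1$osi, 0, tolerance = 1e-12)
  d2 <- osi_dsi(angles16, 1 + cos(2 * (angles16 - 0.7)))
  expect_equal(d2$osi, 0.5, tolerance = 1e-12)
  expect_equal(d2$dsi, 0, tolerance = 1e-12)
  # scale invariance; all-mass-at-one-angle gives DSI = 1
  set.seed(1)
  r <- runif(16)
  expect_equal(osi_dsi(angles16, r)$osi, osi_dsi(angles16, 7 * r)$osi, tolerance = 1e-12)
  delta <- rep(0, 16); delta[4] <- 3
  expect_equal(osi_dsi(angles16, delta)$dsi, 1, tolerance = 1e-12)
  expect_false(osi_dsi(angles16, rep(0, 16))$defined)
})

test_that("the von Mises mixture fit recovers generating parameters", {
  r <- cortexcore:::von_mises_mixture(angles16, 1.0, 2, 1, 0.3, 0.1)
  f <- fit_von_mises(angles16, r)
  expect_equal(f$mu, 1.0, tolerance = 1e-3)
  expect_equal(f$kappa, 2, tolerance = 1e-3)
  expect_equal(f$alpha, 1, tolerance = 1e-3)
  expect_equal(f$beta, 0.3, tolerance = 1e-3)
  expect_equal(f$gamma, 0.1, tolerance = 1e-3)
  expect_lt(f$residual, 1e-6)
  expect_equal(f$pref_orientation, (1.0 + pi / 2) %% pi, tolerance = 1e-3)
  # alpha >= beta enforced by lobe swap
  r2 <- cortexcore:::von_mises_mixture(angles16, 1.0, 2, 0.3, 1, 0.1)
  f2 <- fit_von_mises(angles16, r2)
  expect_gte(f2$alpha, f2$beta)
  expect_equal(wrap_angle(f2$mu - (1.0 + pi)), 0, tolerance = 1e-3)
  # symmetric curve: orientation well-defined modulo pi
  r3 <- cortexcore:::von_mises_mixture(angles16, 0.6, 3, 0.8, 0.8, 0.2)
  f3 <- fit_von_mises(angles16, r3)
  expect_lt(min(abs(wrap_angle(f3$mu - 0.6)), abs(wrap_angle(f3$mu - 0.6 - pi))), 1e-2)
  # flat curve flagged
  expect_equal(fit_von_mises(angles16, rep(1, 16))$flag, "low_modulation")
  expect_error(fit_von_mises(c(0, 1, 2, 0, 1), runif(5)), "distinct")
})

test_that("angular deltas wrap correctly and stay in range", {
  d0 <- angular_deltas(0.4, 0.4)
  expect_equal(d0$delta_direction, 0)
  expect_equal(d0$delta_orientation, 0)
  # opposite directions share an orientation
  dop <- angular_deltas(0, pi)
  expect_equal(dop$delta_direction, pi, tolerance = 1e-12)
  expect_equal(dop$delta_orientation, 0, tolerance = 1e-6)
  # 10 vs 350 degrees: 20 degrees apart
  d20 <- angular_deltas(10 * pi / 180, 350 * pi / 180)
  expect_equal(d20$delta_direction * 180 / pi, 20, tolerance = 1e-9)
  # symmetry and range bounds over random pairs
  set.seed(2)
  for (i in 1:30) {
    a <- runif(1, 0, 2 * pi); b <- runif(1, 0, 2 * pi)
    ab <- angular_deltas(a, b); ba <- angular_deltas(b, a)
    expect_equal(ab$delta_direction, ba$delta_direction, tolerance = 1e-12)
    expect_equal(ab$delta_orientation, ba$delta_orientation, tolerance = 1e-12)
    expect_true(ab$delta_direction >= 0 && ab$delta_direction <= pi)
    expect_true(ab$delta_orientation >= 0 && ab$delta_orientation <= pi / 2 + 1e-12)
  }
})

test_that("the STA weights stimulus deviation by response", {
  set.seed(3)
  frames <- array(127L, c(40, 10, 12))
  frames[11:19, 4, 7] <- 0L # one dark event
  resp <- numeric(40)
  resp[11:19] <- 2 # responds only then (lag 0)
  sta <- compute_sta(frames, resp, lag = 0)
  expect_true(sta$defined)
  pk <- which(sta$map == max(sta$map), arr.ind = TRUE)[1, ]
  expect_equal(unname(pk), c(4, 7))
  # constant response: STA equals the time-average energy map
  stc <- compute_sta(frames, rep(1, 40), lag = 0)
  manual <- apply(abs(frames - 127.5), c(2, 3), mean)
  expect_equal(stc$map, manual, tolerance = 1e-12)
  expect_false(compute_sta(frames, rep(0, 40))$defined)
})

test_that("STA moments and SSI match closed forms", {
  # uniform mass: discrete uniform variances (H^2-1)/12, (W^2-1)/12
  u <- matrix(1, 5, 9)
  m <- sta_moments_ssi(u)
  expect_equal(diag(m$sigma), c((25 - 1) / 12, (81 - 1) / 12), tolerance = 1e-12)
  # isotropic Gaussian, sigma = 3 px: Sigma ~ diag(9, 9), SSI ~ -log 81
  h <- 61
  gm <- exp(-((row(diag(h)) - 31)^2 + (col(diag(h)) - 31)^2) / 18)
  mg <- sta_moments_ssi(gm)
  expect_equal(diag(mg$sigma), c(9, 9), tolerance = 1e-3)
  expect_equal(mg$ssi, -log(81), tolerance = 1e-3)
  # all mass on one pixel: flagged infinite selectivity
  one <- matrix(0, 4, 4); one[2, 3] <- 5
  m1 <- sta_moments_ssi(one)
  expect_true(m1$degenerate)
  expect_identical(m1$ssi, Inf)
  # coordinate rescaling shifts SSI by -log of the squared cell area
  m2 <- sta_moments_ssi(gm, cell_size = c(0.5, 0.5))
  expect_equal(m2$ssi, mg$ssi - log(0.5^4), tolerance = 1e-9)
})

test_that("SSI decreases under isotropic blurring", {
  h <- 41
  base <- exp(-((row(diag(h)) - 21)^2 + (col(diag(h)) - 21)^2) / 8)
  ssis <- sapply(c(1, 2, 3.5), function(s) {
    m <- exp(-((row(diag(h)) - 21)^2 + (col(diag(h)) - 21)^2) / (2 * s^2))
    sta_moments_ssi(m)$ssi
  })
  expect_true(all(diff(ssis) < 0))
})

test_that("the 2D Gaussian fit recovers its generating receptive field", {
  h <- 25; w <- 31
  rows <- matrix(seq_len(h), h, w); cols <- matrix(rep(seq_len(w), each = h), h, w)
  S <- matrix(c(6, 2, 2, 4), 2, 2)
  Si <- solve(S)
  dr <- rows - 14.3; dc <- cols - 19.7
  m <- 2.5 * exp(-(Si[1,1]*dr^2 + 2*Si[1,2]*dr*dc + Si[2,2]*dc^2) / 2) + 0.3
  fit <- fit_spatial_gaussian(m)
  expect_equal(unname(fit$mu), c(14.3, 19.7), tolerance = 1e-3)
  expect_equal(fit$sigma, S, tolerance = 1e-2)
  expect_equal(fit$alpha, 2.5, tolerance = 1e-3)
  expect_equal(fit$gamma, 0.3, tolerance = 1e-3)
  expect_equal(fit$flag, "ok")
  expect_equal(delta_location(fit, fit), 0)
  # flat map flagged
  expect_equal(fit_spatial_gaussian(matrix(1, 10, 10))$flag, "low_amplitude")
})

test_that("simulated battery responses recover the population's preferred directions", {
  mon <- monitor_geometry(width_px = 64L, height_px = 36L)
  pop <- make_population(25, seed = 5)
  curves <- matrix(0, 16, 25)
  for (i in 1:16) {
    st <- directional_pink_noise(angles16[i], 1.5, 30, mon, seed = 100 + i)
    beh <- list(treadmill = rep(0, 45), pupil_d = rep(0, 45))
    r <- simulate_responses(pop, st$frames, beh, mon, noise = "none")
    curves[i, ] <- colMeans(r[6:45, ])
  }
  errs <- sapply(1:25, function(n) {
    f <- fit_von_mises(angles16, curves[, n])
    angular_deltas(f$mu, pop$pref_direction[n])$delta_direction * 180 / pi
  })
  ds <- pop$direction_selectivity
  expect_lte(median(errs[ds > 0.3]), 15)
  # DSI estimates track ground-truth direction selectivity
  dsis <- sapply(1:25, function(n) osi_dsi(angles16, curves[, n])$dsi)
  expect_gt(cor(dsis, ds), 0.8)
})
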