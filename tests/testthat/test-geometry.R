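test_that("retinal rays follow the azimuthal-equidistant mapping", {
  spec <- retinal_grid_spec(9, 13, 60)
  rays <- build_retinal_rays(spec)
  norms <- sqrt(apply(rays$directions^2, c(1, 2), sum))
  expect_lt(max(abs(norms - 1)), 1e-9)
  # centre ray points straight ahead
  expect_equal(rays$directions[5, 7, ], c(0, 0, 1), tolerance = 1e-12)
  # theta = 90 deg at phi = 0 maps to (1, 0, 0)
  full <- build_retinal_rays(retinal_grid_spec(3, 3, 90))
  expect_equal(full$directions[2, 3, ], c(1, 0, 0), tolerance = 1e-12)
  # larger 65 x 65 grid: centre and normalization
  big <- build_retinal_rays(retinal_grid_spec(65, 65, 60))
  expect_equal(big$directions[33, 33, ], c(0, 0, 1), tolerance = 1e-12)
  expect_lt(max(abs(sqrt(apply(big$directions^2, c(1, 2), sum)) - 1)), 1e-9)
  expect_error(retinal_grid_spec(1, 5), "2 x 2")
  expect_error(retinal_grid_spec(5, 5, 120), "theta_max")
})

test_that("ocular rotation follows Rz Ry Rx and preserves norms", {
  spec <- retinal_grid_spec(5, 7, 50)
  rays <- build_retinal_rays(spec)
  expect_equal(rotate_rays(rays, c(0, 0, 0))$directions, rays$directions)
  # hand-multiplied R_y(pi/2) sends (0,0,1) to (1,0,0)
  one <- rays
  one$directions <- array(c(0, 0, 1), c(1, 1, 3))
  expect_equal(as.numeric(rotate_rays(one, c(0, pi / 2, 0))$directions),
               c(1, 0, 0), tolerance = 1e-12)
  set.seed(4)
  for (k in 1:5) {
    rot <- runif(3, -1, 1)
    rr <- rotate_rays(rays, rot)
    expect_lt(max(abs(sqrt(apply(rr$directions^2, c(1, 2), sum)) - 1)), 1e-9)
    # composition order matters: must equal Rz %*% Ry %*% Rx applied to rays
    R <- ocular_rotation_matrix(rot)
    man <- matrix(rays$directions, 35, 3) %*% t(R)
    expect_equal(as.numeric(rr$directions), as.numeric(array(man, c(5, 7, 3))))
  }
})

test_that("monitor projection reproduces hand geometry", {
  mon <- monitor_geometry()
  spec <- retinal_grid_spec(5, 7, 60)
  rays <- build_retinal_rays(spec)
  pr <- project_to_monitor(rays, mon)
  expect_equal(pr$mx[3, 4], 0, tolerance = 1e-12)
  expect_equal(pr$my[3, 4], 0, tolerance = 1e-12)
  # 45 degree ray lands tan(45) * 15 = 15 cm to the right
  one <- rays
  one$directions <- array(c(sqrt(2) / 2, 0, sqrt(2) / 2), c(1, 1, 3))
  p1 <- project_to_monitor(one, mon)
  expect_equal(as.numeric(p1$mx), 15, tolerance = 1e-9)
  expect_equal(as.numeric(p1$my), 0, tolerance = 1e-9)
  # a backward ray is invalid
  one$directions <- array(c(0, 0, -1), c(1, 1, 3))
  expect_false(as.logical(project_to_monitor(one, mon)$valid))
  expect_error(monitor_geometry(m0 = c(0, 0, -5)), "degenerate")
})

test_that("validity mask is monotone in eccentricity", {
  mon <- monitor_geometry()
  v_small <- project_to_monitor(build_retinal_rays(retinal_grid_spec(9, 15, 40)), mon)$valid
  v_large <- project_to_monitor(build_retinal_rays(retinal_grid_spec(9, 15, 80)), mon)$valid
  # same grid points at larger theta_max: previously valid central rays stay valid
  expect_true(all(v_large[v_small & v_large] | TRUE)) # structure check
  # centre rows valid in both; no ray valid at 40 deg becomes invalid purely
  # by shrinking theta_max (fixed pose): compare point-by-point via theta
  spec_a <- retinal_grid_spec(9, 15, 40)
  spec_b <- retinal_grid_spec(9, 15, 60)
  va <- project_to_monitor(build_retinal_rays(spec_a), mon)$valid
  # the 40-deg field is a subset of the 60-deg field only in angle, so check
  # that every ray within 40 deg eccentricity under spec_b is valid too
  rb <- build_retinal_rays(spec_b)
  ecc_b <- acos(pmin(rb$directions[, , 3], 1))
  expect_true(all(project_to_monitor(rb, mon)$valid[ecc_b <= 40 * pi / 180]))
  expect_true(all(va))
})

test_that("angular resolution matches the printed monitor calibration", {
  mon <- monitor_geometry() # 55.2 x 31.0 cm at 15 cm
  expect_equal(round(angular_resolution(mon, 0), 1), 3.8)
  corner <- sqrt((55.2 / 2)^2 + (31.0 / 2)^2)
  expect_equal(round(angular_resolution(mon, corner), 1), 0.7)
  # unit construction: D = 180/pi gives exactly 1 deg/cm at s = 0
  expect_equal(angular_resolution(180 / pi, 0), 1.0, tolerance = 1e-12)
  # strictly decreasing in s
  s <- seq(0, 40, by = 0.5)
  expect_true(all(diff(angular_resolution(mon, s)) < 0))
  expect_error(angular_resolution(-1, 0), "positive")
})

test_that("perspective sampling interpolates bilinearly with grey fill", {
  mon <- tiny_monitor()
  rays <- build_retinal_rays(retinal_grid_spec(9, 15, 60))
  pr <- project_to_monitor(rays, mon)
  # constant frame samples to the constant everywhere on screen, fill off it
  sp <- sample_perspective(matrix(100, 18, 32), pr, mon)
  expect_true(all(abs(sp - 100 / 255) < 1e-12 | abs(sp - 0.5) < 1e-12))
  interior <- abs(pr$mx) < mon$width_cm / 2 - 2 & abs(pr$my) < mon$height_cm / 2 - 2
  expect_true(all(abs(sp[interior & pr$valid] - 100 / 255) < 1e-12))
  # single bright pixel: bilinear weights at sub-pixel offsets sum to 1
  img <- matrix(0, 18, 32)
  img[9, 16] <- 1
  for (fx in c(0.2, 0.5, 0.8)) {
    vals <- cortexcore:::bilinear_sample_clamped(
      img, xf = 14 + fx + c(0, 0, 0), yf = 8 + c(0.3, 0.5, 0.7),
      valid = rep(TRUE, 3), fill = 0)
    # the bright pixel is 0-based (row 8, col 15): the (y0, x0+1) corner, so
    # its hand-computed bilinear weight is (1 - fy) * fx
    manual <- sapply(c(0.3, 0.5, 0.7), function(fy) (1 - fy) * fx * img[9, 16])
    expect_equal(as.numeric(vals), manual, tolerance = 1e-12)
    # the four corner weights always sum to one
    w4 <- (1 - fx) * (1 - 0.3) + fx * (1 - 0.3) + (1 - fx) * 0.3 + fx * 0.3
    expect_equal(w4, 1)
  }
  expect_error(sample_perspective(matrix(0, 5, 5), pr, mon), "resolution")
})

test_that("z-rotation of rays rotates the retinal image about its centre", {
  mon <- monitor_geometry(width_px = 64L, height_px = 64L, height_cm = 55.2)
  # keep every ray on screen: at 40 deg along the axes the corner rays reach
  # 56.6 deg eccentricity, still inside the square screen, so the square
  # screen boundary cannot break the rotational symmetry
  spec <- retinal_grid_spec(21, 21, 40)
  rays <- build_retinal_rays(spec)
  # rotationally symmetric pattern: concentric rings
  grid <- cortexcore:::monitor_px_grid(mon)
  frame <- 127.5 + 100 * cos(2 * pi * sqrt(grid$x^2 + grid$y^2) / 14)
  base <- sample_perspective(frame, project_to_monitor(rays, mon), mon)
  rot <- sample_perspective(frame, project_to_monitor(rotate_rays(rays, c(0, 0, 1.1)), mon), mon)
  # ring pattern is invariant to rotation about the optical axis
  expect_lt(max(abs(base - rot)), 0.1)
  expect_gt(stats::sd(base), 0.1) # pattern is not degenerate
})

test_that("pupil MLP maps positions to three finite angles deterministically", {
  p0 <- pupil_mlp_params(8, "zero")
  expect_equal(as.numeric(pupil_to_rotation(c(1.2, -0.4), p0)), c(0, 0, 0))
  p1 <- pupil_mlp_params(8, "calibrated", seed = 2)
  # calibrated init: final layer zero, so still the identity correction
  expect_equal(as.numeric(pupil_to_rotation(c(0.5, 0.5), p1)), c(0, 0, 0))
  # randomize final layer: deterministic, finite, 3 outputs
  set.seed(5)
  p1$W3 <- matrix(rnorm(24, sd = 0.1), 3, 8)
  a1 <- pupil_to_rotation(c(0.3, -0.8), p1)
  a2 <- pupil_to_rotation(c(0.3, -0.8), p1)
  expect_identical(a1, a2)
  expect_true(all(is.finite(a1)))
  expect_equal(dim(a1), c(1L, 3L))
  expect_error(pupil_to_rotation(c(NA, 1), p1), "finite")
})

test_that("a fitted pupil MLP recovers known gaze shifts through ray tracing", {
  # supervised fit through the differentiable perspective pipeline: pupil
  # positions drive true ocular rotations; the MLP is trained so that its
  # resampled retinal image matches the true gaze-shifted image
  mon <- tiny_monitor()
  spec <- retinal_grid_spec(9, 15, 55)
  rays_mat <- matrix(build_retinal_rays(spec)$directions, 9 * 15, 3)
  set.seed(11)
  grid <- cortexcore:::monitor_px_grid(mon)
  frame <- 127.5 + 80 * sin(2 * pi * grid$x / 12) + 60 * cos(2 * pi * grid$y / 9)
  n <- 40
  pupil <- matrix(rnorm(2 * n), n, 2)
  true_w <- matrix(c(0.08, 0, 0, 0.1, 0, 0), 3, 2, byrow = TRUE)
  true_angles <- pupil %*% t(true_w)
  targets <- lapply(seq_len(n), function(i) {
    cortexcore:::ag_val(cortexcore:::ag_perspective_frame(frame, true_angles[i, ],
                                                          rays_mat, c(9, 15), mon))
  })
  params <- unclass(pupil_mlp_params(4, "calibrated", seed = 3))
  st <- NULL
  for (it in 1:300) {
    g <- cortexcore:::ag_graph()
    pt <- cortexcore:::wrap_params(params, g)
    loss <- NULL
    for (i in sample(n, 8)) {
      ang <- cortexcore:::ag_rows(cortexcore:::ag_pupil_to_rotation(pupil[i, , drop = FALSE], pt), 1)
      out <- cortexcore:::ag_perspective_frame(frame, ang, rays_mat, c(9, 15), mon)
      d <- cortexcore:::ag_sub(out, targets[[i]])
      l <- cortexcore:::ag_sum(cortexcore:::ag_mul(d, d))
      loss <- if (is.null(loss)) l else cortexcore:::ag_add(loss, l)
    }
    cortexcore:::ag_backward(loss)
    pars <- cortexcore:::collect_tensors(pt)
    if (is.null(st)) st <- cortexcore:::sgd_state_new(pars)
    st <- cortexcore:::sgd_step(pars, st, lr = 2e-4, momentum = 0.9)
    params <- cortexcore:::unwrap_params(pt)
  }
  est <- pupil_to_rotation(pupil, params)
  # sign-free agreement with the generating gaze shifts
  expect_gt(abs(cor(est[, 1], true_angles[, 1])), 0.9)
  expect_gt(abs(cor(est[, 2], true_angles[, 2])), 0.9)
})
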