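test_that("poisson loss evaluates the printed sum with the y=0 convention", {
  expect_equal(poisson_loss(1, 0), 1)
  expect_equal(poisson_loss(1, 1), 1)
  expect_equal(poisson_loss(c(2, 3), c(1, 2)), (2 - log(2)) + (3 - 2 * log(3)))
  expect_equal(round(poisson_loss(c(2, 3), c(1, 2)), 4), 2.1096)
  expect_error(poisson_loss(c(1, 0), c(0, 0)), "positive")
})

test_that("the learning-rate schedule is piecewise with a warm restart", {
  cfg <- train_config(seed = 1) # 200 epochs: 10 warmup / 90 cosine / 100 cosine
  expect_equal(lr_at(0, 0, cfg), 0)
  expect_equal(lr_at(5, 0, cfg), cfg$base_lr / 2)
  expect_equal(lr_at(55, 0, cfg), cfg$base_lr / 2, tolerance = 1e-12) # cos midpoint
  expect_equal(lr_at(100, 0, cfg), cfg$base_lr) # warm restart
  expect_equal(lr_at(150, 0, cfg), cfg$base_lr / 2, tolerance = 1e-12)
  expect_error(lr_at(200, 0, cfg), "range")
  expect_error(lr_at(-1, 0, cfg), "range")
  # continuity within pieces at iteration granularity; single jump at restart
  grid <- seq(0, 199.99, by = 0.01)
  vals <- sapply(grid, function(e) lr_at(floor(e), (e - floor(e)) * cfg$iters_per_epoch, cfg))
  jumps <- which(abs(diff(vals)) > cfg$base_lr * 0.01)
  expect_equal(length(jumps), 1L)
  expect_equal(grid[jumps + 1], 100)
  # invalid phase partitions are rejected
  expect_error(train_config(epochs = 100, warmup_epochs = 10,
                            first_cosine_epochs = 50, second_cosine_epochs = 50),
               "must equal")
})

desk_session <- function(seed = 23) {
  make_session(session_config(n_neurons = 10L, train_minutes = 0.5,
                              test_clips = 1L, test_clip_s = 2, test_repeats = 2L,
                              battery_directions = 2L, battery_repeats = 1L,
                              battery_clip_s = 1, dot_events = 3L),
               seed = seed)
}

micro_train_cfg <- function(...) {
  desk_train_config(epochs = 2L, iters_per_epoch = 4L, warmup_epochs = 1L,
                    first_cosine_epochs = 1L, second_cosine_epochs = 0L,
                    clip_frames = 10L, ...)
}

test_that("training reduces the loss and is bitwise reproducible", {
  s <- desk_session()
  cfg <- tiny_cfg()
  model <- encoder_init(cfg, 10L, mon = s$monitor, seed = 2)
  tc <- micro_train_cfg(epochs = 6L, warmup_epochs = 1L, first_cosine_epochs = 2L,
                        second_cosine_epochs = 3L, base_lr = 0.1, seed = 4,
                        batch_size = 1L)
  # a single training window makes the per-iteration losses comparable
  m1 <- train_model(model, s, tc, train_fraction = 1e-9)
  expect_false(is.null(m1$history))
  idx <- cortexcore:::split_frames(s, "train")[1:10]
  y <- s$responses[idx, ]
  pred <- predict_responses(m1, s$stimulus$frames[idx, , , drop = FALSE],
                            cortexcore:::slice_behavior(s$behavior, idx),
                            s$behavior$pupil_xy[idx, , drop = FALSE])
  # the fitted model beats the best constant predictor on its own window
  const <- poisson_loss(matrix(colMeans(y) + 1e-9, 10, 10, byrow = TRUE), y)
  expect_lt(poisson_loss(pred, y), const)
  # same seed: bitwise-identical parameter trajectory
  m2 <- train_model(model, s, tc, train_fraction = 1e-9)
  expect_identical(m1$params, m2$params)
  # different seed: different trajectory
  tc3 <- tc; tc3$seed <- 5L
  m3 <- train_model(model, s, tc3, train_fraction = 1e-9)
  expect_false(identical(m1$params, m3$params))
})

test_that("a single repeated batch is overfit towards its Poisson optimum", {
  s <- desk_session()
  cfg <- tiny_cfg()
  # a capacity check: quiesce the readout position jitter so the repeated
  # batch is seen through stable features
  model <- encoder_init(tiny_cfg(readout_sd_init = 0.02), 10L,
                        mon = s$monitor, seed = 3)
  tc <- micro_train_cfg(epochs = 12L, iters_per_epoch = 8L, warmup_epochs = 1L,
                        first_cosine_epochs = 5L, second_cosine_epochs = 6L,
                        batch_size = 1L, base_lr = 0.1, seed = 9)
  m <- train_model(model, s, tc, train_fraction = 1e-9) # single start window
  idx <- cortexcore:::split_frames(s, "train")[1:10]
  y <- s$responses[idx, ]
  pred <- predict_responses(m, s$stimulus$frames[idx, , , drop = FALSE],
                            cortexcore:::slice_behavior(s$behavior, idx),
                            s$behavior$pupil_xy[idx, , drop = FALSE])
  fitted_loss <- poisson_loss(pred, y)
  # bounded below by the saturated model (r = y), and the fit recovers a
  # sizeable share of the gap between the constant predictor and saturation
  opt <- poisson_loss(pmax(y, 1e-9), y)
  const <- poisson_loss(matrix(colMeans(y) + 1e-9, 10, 10, byrow = TRUE), y)
  expect_gte(fitted_loss, opt - 1e-9)
  expect_lt(fitted_loss, const - 0.15 * (const - opt))
})

test_that("transfer freezes the core bit-for-bit and fits the rest", {
  s <- desk_session(seed = 29)
  cfg <- tiny_cfg()
  foundation <- encoder_init(cfg, 10L, mon = s$monitor, seed = 5)
  tc <- micro_train_cfg(base_lr = 0.05, seed = 6)
  fit <- train_model(foundation, s, tc)
  s2 <- desk_session(seed = 31)
  tr <- transfer_model(fit, s2, micro_train_cfg(base_lr = 0.05, seed = 7), seed = 8)
  for (h in seq_along(tr$params$heads)) {
    expect_identical(tr$params$heads[[h]]$ff, fit$params$heads[[h]]$ff)
    expect_identical(tr$params$heads[[h]]$cells, fit$params$heads[[h]]$cells)
  }
  # non-core components did move
  init <- encoder_init(cfg, 10L, mon = s2$monitor, seed = 8)
  expect_false(identical(tr$params$heads[[1]]$readout$w, init$params$heads[[1]]$readout$w))
  # the trainable mask is exactly the complement of the core
  paths <- vapply(cortexcore:::flatten_params(fit$params), function(l) l$path, "")
  mask <- vapply(paths, cortexcore:::transfer_trainable, TRUE)
  core <- grepl("\\.(ff|cells)\\.", paths)
  expect_identical(unname(mask), !core)
})

test_that("transfer with zero training remains at a valid initialization", {
  s <- desk_session(seed = 37)
  foundation <- encoder_init(tiny_cfg(), 10L, mon = s$monitor, seed = 5)
  tc <- micro_train_cfg(epochs = 1L, iters_per_epoch = 1L, warmup_epochs = 1L,
                        first_cosine_epochs = 0L, second_cosine_epochs = 0L,
                        base_lr = 0) # zero step size = no-op training
  m <- transfer_model(foundation, s, tc, seed = 11)
  inp_frames <- s$stimulus$frames[1:6, , , drop = FALSE]
  p <- predict_responses(m, inp_frames,
                         cortexcore:::slice_behavior(s$behavior, 1:6),
                         s$behavior$pupil_xy[1:6, ])
  expect_true(all(is.finite(p)) && all(p > 0))
})

test_that("readout position covariance shrinks over training on clean signal", {
  s <- desk_session(seed = 41)
  cfg <- tiny_cfg()
  model <- encoder_init(cfg, 10L, mon = s$monitor, seed = 13)
  trace0 <- median(rowSums(model$params$readout_pos$L^2))
  tc <- micro_train_cfg(epochs = 8L, iters_per_epoch = 6L, warmup_epochs = 1L,
                        first_cosine_epochs = 3L, second_cosine_epochs = 4L,
                        base_lr = 0.1, seed = 15)
  m <- train_model(model, s, tc)
  trace1 <- median(rowSums(m$params$readout_pos$L^2))
  expect_lt(trace1, trace0)
})
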