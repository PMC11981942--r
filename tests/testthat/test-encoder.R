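test_that("zeroed modulation LSTM follows the sigma(0) gate algebra exactly", {
  m <- 6L
  p0 <- list(Wx = matrix(0, 4 * m, 3), Wh = matrix(0, 4 * m, m), b = numeric(4 * m))
  st <- modulation_step(c(1.3, -0.2, 0.8), NULL, p0)
  expect_identical(st$h, rep(0, m)) # 0.5 * tanh(0.5 * tanh(0)) = 0
  expect_identical(st$c, rep(0, m))
  # nonzero prior cell state, zero weights: c' = 0.5 c, h' = 0.5 tanh(0.5 c)
  c0 <- c(0.4, -1, 2, 0.1, 0, -0.3)
  st2 <- modulation_step(c(0, 0, 0), list(h = rep(0, m), c = c0), p0)
  expect_equal(st2$c, 0.5 * c0, tolerance = 1e-12)
  expect_equal(st2$h, 0.5 * tanh(0.5 * c0), tolerance = 1e-12)
  expect_error(modulation_step(c(NA, 1, 1), NULL, p0), "finite")
  # tiling broadcasts the identical vector everywhere
  tiled <- tile_modulation(c(1, 2, 3), 4, 5)
  expect_equal(dim(tiled), c(4L, 5L, 3L))
  expect_true(all(tiled[, , 2] == 2))
  expect_equal(tile_modulation(c(1, 2, 3), 8, 10)[1, 1, ], c(1, 2, 3))
})

test_that("zeroed Conv-LSTM gates reduce to the 0.5-cascade closed form", {
  cfg <- tiny_cfg()
  cp0 <- zeroed(cortexcore:::init_cell_params(cfg, cf = 25L))
  set.seed(1)
  d <- c(2L, 3L)
  Hf <- array(rnorm(prod(d) * 25), c(d, 25))
  Hm <- array(rnorm(prod(d) * 6), c(d, 6))
  C0 <- array(rnorm(prod(d) * 4), c(d, 4))
  st <- list(h = list(array(0, c(d, 4)), array(0, c(d, 4))), c = list(C0, 2 * C0))
  st2 <- convlstm_step(Hf, Hm, st, list(cp0, cp0), cfg)
  expect_equal(st2$c[[1]], 0.5 * C0, tolerance = 1e-12)
  expect_equal(st2$c[[2]], C0, tolerance = 1e-12)
  expect_equal(st2$h[[1]], 0.5 * tanh(0.5 * C0), tolerance = 1e-12)
  # hidden maps bounded by the output gate and tanh
  cp <- cortexcore:::init_cell_params(cfg, cf = 25L)
  st3 <- convlstm_step(Hf, Hm, NULL, list(cp, cp), cfg)
  expect_true(all(abs(unlist(st3$h)) < 1))
})

test_that("core output concatenates cell hidden maps in stable order", {
  h1 <- array(rnorm(12), c(2, 3, 2))
  h2 <- array(rnorm(18), c(2, 3, 3))
  st <- list(h = list(h1, h2))
  out <- core_output(st)
  expect_equal(dim(out), c(2L, 3L, 5L))
  expect_equal(out[, , 1:2], h1)
  expect_equal(out[, , 3:5], h2)
  expect_identical(out, core_output(st))
  # configured full-size channel count: 2 cells x 256 channels = 512
  st512 <- list(h = list(array(0, c(2, 2, 256)), array(0, c(2, 2, 256))))
  expect_equal(dim(core_output(st512))[3], 512L)
})

test_that("readout responses are positive, deterministic, and position-faithful", {
  H <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  pos <- list(mu = matrix(c(0.2, -0.3, 0, 0.5), 2, 2), L = cbind(c(0.3, 0.3), 0, c(0.3, 0.3)))
  w0 <- list(w = matrix(0, 2, 3), b = c(0, 0))
  expect_equal(readout_response(H, pos, w0), c(1, 1)) # exp(0)
  # spatially constant map: response independent of position
  Hc <- array(rep(c(1, -2, 0.5), each = 20), c(4, 5, 3))
  wts <- list(w = matrix(rnorm(6), 2, 3), b = c(0.1, -0.2))
  r1 <- readout_response(Hc, pos, wts)
  pos2 <- pos; pos2$mu <- matrix(c(-0.7, 0.6, 0.4, -0.1), 2, 2)
  expect_equal(r1, readout_response(Hc, pos2, wts), tolerance = 1e-12)
  # eval deterministic; train deterministic given the seed
  expect_identical(readout_response(H, pos, wts), readout_response(H, pos, wts))
  t1 <- readout_response(H, pos, wts, mode = "train", seed = 5)
  t2 <- readout_response(H, pos, wts, mode = "train", seed = 5)
  expect_identical(t1, t2)
  expect_false(identical(t1, readout_response(H, pos, wts, mode = "train", seed = 6)))
  expect_true(all(t1 > 0))
})

test_that("feedforward is causal with the configured spatial reduction", {
  cfg <- tiny_cfg()
  model <- tiny_model(cfg = cfg)
  set.seed(4)
  clip <- array(runif(8 * 17 * 25), c(8, 17, 25))
  out <- feedforward(clip, model$params$heads[[1]], cfg)
  expect_equal(dim(out)[2:3], c(17L %/% 8L, 25L %/% 8L)) # three x2 poolings
  expect_equal(dim(out)[4], 1L + 2L * 3L * cfg$ff_growth)
  # future perturbation cannot reach the past
  clip2 <- clip
  clip2[6, , ] <- runif(17 * 25)
  out2 <- feedforward(clip2, model$params$heads[[1]], cfg)
  expect_identical(out[1:5, , , ], out2[1:5, , , ])
  expect_false(identical(out[6, , , ], out2[6, , , ]))
  # constant input settles to a time-constant output after the warm-up
  cc <- array(0.7, c(8, 17, 25))
  oc <- feedforward(cc, model$params$heads[[1]], cfg)
  expect_equal(oc[7, , , ], oc[8, , , ], tolerance = 1e-12)
  expect_error(feedforward(array(0, c(0, 4, 4)), model$params$heads[[1]], cfg))
})

test_that("end-to-end predictions are causal, positive and seed-stable", {
  model <- tiny_model(n = 5)
  inp <- rand_inputs(7)
  out <- encoder_forward(model, inp$frames, inp$behavior, inp$pupil_xy)
  expect_true(all(out$rates > 0))
  out_b <- encoder_forward(model, inp$frames, inp$behavior, inp$pupil_xy)
  expect_identical(out$rates, out_b$rates)
  # perturb stimulus and behaviour after t = 4
  inp2 <- inp
  inp2$frames[6, , ] <- sample(0:255, 18 * 32, TRUE)
  inp2$behavior$treadmill[5] <- 50
  inp2$pupil_xy[7, ] <- c(3, -3)
  out2 <- encoder_forward(model, inp2$frames, inp2$behavior, inp2$pupil_xy)
  expect_identical(out$rates[1:4, , ], out2$rates[1:4, , ])
  expect_false(identical(out$rates[5, , ], out2$rates[5, , ]))
})

test_that("the CvT-LSTM variant runs, is bounded, and degrades to known forms", {
  cfg <- tiny_cfg(variant = "cvtlstm")
  model <- tiny_model(n = 3, cfg = cfg)
  inp <- rand_inputs(4)
  out <- encoder_forward(model, inp$frames, inp$behavior, inp$pupil_xy)
  expect_true(all(out$rates > 0))
  # guard: the conv-lstm configured model refuses the cvt step
  expect_error(cvt_lstm_step(array(0, c(2, 3, 25)), array(0, c(2, 3, 16)), NULL,
                             list(), tiny_cfg()), "cvtlstm")
  # uniform Q and K: attention output is the spatial mean of V at every token
  d <- c(3L, 4L); ch <- 4L
  cp <- cortexcore:::init_cell_params(cfg, cf = 25L)
  cp$Wq[] <- 0; cp$Wk[] <- 0
  Z <- cortexcore:::ag_tensor(array(rnorm(prod(d) * ch), c(d, ch)))
  A <- cortexcore:::ag_val(cortexcore:::spatial_attention(Z, cp))
  V <- cortexcore:::ag_val(cortexcore:::ag_conv2d(Z, cortexcore:::ag_tensor(cp$Wv)))
  vm <- apply(matrix(V, prod(d), ch), 2, mean)
  for (k in seq_len(ch)) expect_equal(as.numeric(A[, , k]), rep(vm[k], prod(d)), tolerance = 1e-9)
  # zero value projection: attention contributes nothing
  cp$Wv[] <- 0
  expect_equal(max(abs(cortexcore:::ag_val(cortexcore:::spatial_attention(Z, cp)))), 0)
  # hidden maps bounded
  Hf <- array(rnorm(prod(d) * 25), c(d, 25))
  Hm <- array(rnorm(prod(d) * 16), c(d, 16))
  st <- cvt_lstm_step(Hf, Hm, NULL, list(cortexcore:::init_cell_params(cfg, cf = 25L),
                                         cortexcore:::init_cell_params(cfg, cf = 25L)), cfg)
  expect_true(all(abs(unlist(st$h)) < 1))
})

test_that("the ensemble averages standardized log-responses symmetrically", {
  set.seed(6)
  T <- 30; N <- 5
  heads <- lapply(1:4, function(i) exp(matrix(rnorm(T * N, sd = 0.5), T, N)))
  stats_list <- lapply(heads, function(h) list(mean = colMeans(log(h)),
                                               sd = apply(log(h), 2, sd)))
  # identical heads: ensemble equals any single head
  same <- ensemble_predict(rep(heads[1], 4), rep(stats_list[1], 4))
  expect_equal(same, heads[[1]], tolerance = 1e-12)
  # permutation symmetry
  e1 <- ensemble_predict(heads, stats_list)
  perm <- c(3, 1, 4, 2)
  e2 <- ensemble_predict(heads[perm], stats_list[perm])
  expect_equal(e1, e2, tolerance = 1e-12)
  expect_true(all(e1 > 0))
  # monotone: raising one head's response at a time raises the ensemble
  heads2 <- heads
  heads2[[2]][7, 3] <- heads2[[2]][7, 3] * 2
  e3 <- ensemble_predict(heads2, stats_list)
  expect_gt(e3[7, 3], e1[7, 3])
  expect_equal(e3[-7, -3], e1[-7, -3], tolerance = 1e-12)
  # zero-sd neuron falls back to plain log averaging
  st0 <- stats_list
  for (k in 1:4) st0[[k]]$sd[2] <- 0
  e4 <- ensemble_predict(heads, st0)
  fallback <- exp(Reduce(`+`, lapply(heads, log)) / 4)
  expect_equal(e4[, 2], fallback[, 2], tolerance = 1e-12)
})

test_that("parameter counts match the closed-form shape audit", {
  cfg <- tiny_cfg()
  n <- 7L
  model <- tiny_model(n = n, cfg = cfg)
  g <- cfg$ff_growth; kt <- cfg$ff_kt; ch <- cfg$cell_channels
  mlp <- 8 * 2 + 8 + 8 * 8 + 8 + 3 * 8 + 3
  pos <- n * 2 + n * 3
  mod <- 24 * 3 + 24 * 6 + 24
  ffp <- 0
  cin <- 1
  for (b in 1:3) {
    ffp <- ffp + 9 * cin * kt * g + g + 9 * (cin + g) * kt * g + g
    cin <- cin + 2 * g
  }
  cf <- cin
  cin_mix <- cf + 6 + (2 - 1) * ch
  cells <- 2 * (cin_mix * ch + 9 * 2 * ch * 4 * ch + 4 * ch)
  readout <- n * 2 * ch + n
  expect_equal(count_parameters(model), mlp + pos + mod + ffp + cells + readout)
})
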