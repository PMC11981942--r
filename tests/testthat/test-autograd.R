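# Gradient checks of the reverse-mode tape against central finite
# differences, covering every operation the encoder uses.

ag <- function(name) get(name, envir = asNamespace("cortexcore"))

grad_check <- function(build, x, eps = 1e-6, tol = 1e-6) {
  g <- ag("ag_graph")()
  xt <- ag("ag_param")(x, g)
  loss <- build(xt)
  ag("ag_backward")(loss)
  analytic <- xt$grad
  numeric <- fd_grad(function(v) ag("ag_val")(build(ag("ag_tensor")(v))), x, eps)
  expect_lt(max(abs(analytic - numeric)) / max(1e-8, max(abs(numeric))), tol)
}

test_that("elementwise, linear-algebra and shape ops differentiate correctly", {
  set.seed(1)
  x <- array(rnorm(4 * 6 * 3), c(4, 6, 3))
  A <- matrix(rnorm(12), 3, 4)
  B <- matrix(rnorm(20), 4, 5)
  Gc <- matrix(rnorm(15), 3, 5)
  sum_ <- ag("ag_sum"); mul <- ag("ag_mul")
  grad_check(function(t) sum_(ag("ag_tanh")(mul(t, t))), x)
  grad_check(function(t) sum_(ag("ag_sigmoid")(t)), x)
  grad_check(function(t) sum_(ag("ag_elu")(t)), x)
  grad_check(function(t) sum_(ag("ag_gelu")(t)), x, tol = 1e-5)
  grad_check(function(t) sum_(ag("ag_exp")(ag("ag_scale")(t, 0.3))), x)
  grad_check(function(t) sum_(mul(ag("ag_matmul")(t, B), Gc)), A)
  grad_check(function(t) sum_(mul(ag("ag_softmax_rows")(t), Gc[, 1:4])), A)
  grad_check(function(t) sum_(mul(ag("ag_t")(t), t(Gc[, 1:4]))), A)
  grad_check(function(t) sum_(ag("ag_rowdot")(t, Gc[, 1:4] * 0 + 2)), A)
  R62 <- matrix(rnorm(12), 6, 2)
  grad_check(function(t) sum_(mul(ag("ag_reshape")(t, c(6, 2)), R62)), A)
})

test_that("convolutions, pooling and tiling differentiate correctly", {
  set.seed(2)
  x <- array(rnorm(6 * 8 * 3), c(6, 8, 3))
  w3 <- array(rnorm(3 * 3 * 3 * 4) * 0.3, c(3, 3, 3, 4))
  w1 <- array(rnorm(1 * 1 * 3 * 2), c(1, 1, 3, 2))
  b <- rnorm(4)
  sum_ <- ag("ag_sum")
  grad_check(function(t) sum_(ag("ag_tanh")(ag("ag_conv2d")(t, w3, b))), x)
  grad_check(function(t) sum_(ag("ag_tanh")(ag("ag_conv2d")(x, t, b))), w3)
  grad_check(function(t) sum_(ag("ag_conv2d")(t, w1, NULL)), x)
  grad_check(function(t) sum_(ag("ag_mul")(ag("ag_pool2")(t), ag("ag_pool2")(t))), x)
  grad_check(function(t) sum_(ag("ag_mul")(ag("ag_tile_hw")(t, 4, 5),
                                           ag("ag_tile_hw")(t, 4, 5))), rnorm(3))
  # flat clip variants agree with per-frame application
  T <- 4
  xf <- matrix(rnorm(6 * 8 * T * 3), 6 * 8 * T, 3)
  vflat <- ag("ag_val")(ag("ag_conv2d_flat")(ag("ag_tensor")(xf), w3, b, 6L, 8L, T))
  for (t in seq_len(T)) {
    xt <- array(xf[(t - 1) * 48 + 1:48, ], c(6, 8, 3))
    vt <- ag("ag_val")(ag("ag_conv2d")(ag("ag_tensor")(xt), w3, b))
    expect_equal(array(vflat[(t - 1) * 48 + 1:48, ], c(6, 8, 4)), vt, tolerance = 1e-12)
  }
  grad_check(function(t) sum_(ag("ag_tanh")(ag("ag_conv2d_flat")(t, w3, b, 6L, 8L, T))), xf)
  grad_check(function(t) sum_(ag("ag_mul")(ag("ag_pool2_flat")(t, 6L, 8L, T),
                                           ag("ag_pool2_flat")(t, 6L, 8L, T))), xf)
  grad_check(function(t) sum_(ag("ag_mul")(ag("ag_tshift_flat")(t, 48L, T, 1L),
                                           ag("ag_tshift_flat")(t, 48L, T, 1L))), xf)
})

test_that("readout interpolation differentiates in features and positions", {
  set.seed(3)
  Hm <- array(rnorm(5 * 7 * 3), c(5, 7, 3))
  pos <- matrix(runif(8, -0.8, 0.8), 4, 2)
  sum_ <- ag("ag_sum")
  grad_check(function(t) sum_(ag("ag_tanh")(ag("ag_bilinear_read")(t, pos))), Hm)
  grad_check(function(t) sum_(ag("ag_tanh")(ag("ag_bilinear_read")(Hm, t))), pos)
  # clip variant: positions and stacked maps
  T <- 3
  Hs <- matrix(rnorm(35 * T * 3), 35 * T, 3)
  grad_check(function(t) sum_(ag("ag_tanh")(ag("ag_bilinear_read_clip")(t, pos, 5L, 7L, T))), Hs)
  grad_check(function(t) sum_(ag("ag_tanh")(ag("ag_bilinear_read_clip")(Hs, t, 5L, 7L, T))), pos)
  w <- matrix(rnorm(4 * 3) * 0.3, 4, 3)
  bb <- rnorm(4) * 0.1
  feats <- matrix(rnorm(4 * T * 3), 4 * T, 3)
  grad_check(function(t) sum_(ag("ag_readout_exp_clip")(t, w, bb, T)), feats)
  grad_check(function(t) sum_(ag("ag_readout_exp_clip")(feats, t, bb, T)), w)
  grad_check(function(t) sum_(ag("ag_readout_exp_clip")(feats, w, t, T)), bb)
})

test_that("poisson loss gradient matches finite differences", {
  set.seed(4)
  r <- exp(rnorm(40) * 0.5)
  y <- rpois(40, 1.5)
  g <- ag("ag_graph")()
  rt <- ag("ag_param")(r, g)
  loss <- ag("ag_sum")(ag("ag_sub")(rt, ag("ag_mul")(ag("ag_log")(rt), y)))
  expect_equal(ag("ag_val")(loss), poisson_loss(r, y), tolerance = 1e-12)
  ag("ag_backward")(loss)
  numeric <- fd_grad(function(v) poisson_loss(v, y), r)
  expect_lt(max(abs(rt$grad - numeric)) / max(abs(numeric)), 1e-5)
})

test_that("nesterov SGD minimizes a quadratic and respects gradient clipping", {
  p_val <- c(5, -3)
  st <- NULL
  for (i in 1:150) {
    g <- ag("ag_graph")()
    pt <- ag("ag_param")(p_val, g)
    loss <- ag("ag_sum")(ag("ag_mul")(pt, pt))
    ag("ag_backward")(loss)
    if (is.null(st)) st <- ag("sgd_state_new")(list(pt))
    st <- ag("sgd_step")(list(pt), st, 0.05, 0.9)
    p_val <- pt$value
  }
  expect_lt(max(abs(p_val)), 1e-6)
  # clipping bounds the applied step
  g <- ag("ag_graph")()
  pt <- ag("ag_param")(c(1000, 1000), g)
  loss <- ag("ag_sum")(ag("ag_mul")(pt, pt))
  ag("ag_backward")(loss)
  st2 <- ag("sgd_state_new")(list(pt))
  before <- pt$value
  ag("sgd_step")(list(pt), st2, lr = 1, momentum = 0, clip_norm = 1)
  expect_lt(sqrt(sum((pt$value - before)^2)), 2 + 1e-9)
})
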