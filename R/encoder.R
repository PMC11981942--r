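# The four-module encoding network: gaze-corrected perspective (geometry
# module), behavioural modulation LSTM, a core of causal 3D-convolution
# DenseNet blocks feeding Conv-LSTM (or CvT-LSTM) recurrent cells, and
# factorized per-neuron readouts. One forward implementation serves both
# inference and training: operations constant-fold when no tape is attached.

#' Encoder configuration
#'
#' Defaults describe the full-size architecture: a 37 x 65 retinal grid,
#' three DenseNet blocks (growth 16, two causal 3x3x3 convolution layers per
#' block, x2 spatial pooling after each block), 2 recurrent cells of 256
#' channels (so the core output has C = 512 channels), a 6-unit modulation
#' LSTM, 4 ensemble heads and an 8-unit pupil MLP. [desk_encoder_config()]
#' scales the same architecture down for CPU-scale experiments.
#'
#' @param variant `"convlstm"` or `"cvtlstm"`.
#' @param grid_height,grid_width,theta_max_deg Retinal ray grid.
#' @param ff_growth DenseNet growth rate (channels added per layer).
#' @param ff_blocks Number of DenseNet blocks (x2 pooling after each).
#' @param ff_kt Temporal taps of each causal 3D convolution.
#' @param ff_t_dilation Spacing (frames) between temporal taps; taps reach
#'   `(ff_kt - 1) * ff_t_dilation` frames into the past, lengthening the
#'   temporal receptive field without extra parameters.
#' @param cells,cell_channels Recurrent cells and channels per cell.
#' @param mod_hidden Modulation LSTM hidden size (6 for the Conv-LSTM
#'   variant, 16 for CvT-LSTM, which also drops the pupil derivative input).
#' @param heads Ensemble heads (default 4).
#' @param spatial_grid Append normalized x,y coordinate channels to the
#'   feedforward features entering the recurrent cells.
#' @param mlp_hidden Pupil-MLP hidden units.
#' @param fill Background retinal activation for off-screen rays.
#' @param feature_gain Fixed scale applied to the core output before the
#'   readout, so that roughly unit-variance features reach the exponential
#'   readout (the recurrent gates keep raw hidden maps well inside (-1, 1)).
#' @param readout_sd_init Initial readout-position s.d. as a fraction of the
#'   feature-map extent.
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(variant = c("convlstm", "cvtlstm"),
                           grid_height = 37L, grid_width = 65L, theta_max_deg = 60,
                           ff_growth = 16L, ff_blocks = 3L, ff_kt = 2L,
                           ff_t_dilation = 1L,
                           cells = 2L, cell_channels = 256L,
                           mod_hidden = NULL, heads = 4L, spatial_grid = FALSE,
                           mlp_hidden = 8L, fill = 0.5, feature_gain = 8,
                           readout_sd_init = 0.25) {
  variant <- match.arg(variant)
  if (is.null(mod_hidden)) mod_hidden <- if (variant == "convlstm") 6L else 16L
  structure(list(variant = variant, grid_height = as.integer(grid_height),
                 grid_width = as.integer(grid_width), theta_max_deg = theta_max_deg,
                 ff_growth = as.integer(ff_growth), ff_blocks = as.integer(ff_blocks),
                 ff_kt = as.integer(ff_kt), ff_t_dilation = as.integer(ff_t_dilation),
                 cells = as.integer(cells),
                 cell_channels = as.integer(cell_channels),
                 mod_hidden = as.integer(mod_hidden), heads = as.integer(heads),
                 spatial_grid = spatial_grid, mlp_hidden = as.integer(mlp_hidden),
                 fill = fill, feature_gain = feature_gain,
                 readout_sd_init = readout_sd_init),
            class = "encoder_config")
}

#' Desk-scale encoder configuration
#'
#' The architecture of [encoder_config()] with sizes chosen for single-CPU
#' training: 25 x 41 retinal grid, growth 4, 2 cells x 8 channels (16-channel
#' core output), one head.
#'
#' @param ... Overrides passed to [encoder_config()].
#' @export
desk_encoder_config <- function(...) {
  defaults <- list(grid_height = 25L, grid_width = 41L, ff_growth = 4L,
                   cell_channels = 8L, heads = 1L)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(encoder_config, defaults)
}

# number of input behaviour channels of the modulation LSTM
mod_inputs <- function(config) if (config$variant == "convlstm") 3L else 2L

ff_channels <- function(config) {
  ch <- 1L
  for (b in seq_len(config$ff_blocks)) ch <- ch + 2L * config$ff_growth
  ch
}

core_map_dim <- function(config) {
  h <- config$grid_height; w <- config$grid_width
  for (b in seq_len(config$ff_blocks)) { h <- h %/% 2L; w <- w %/% 2L }
  c(h, w)
}

rand_arr <- function(dims, sd) array(stats::rnorm(prod(dims), sd = sd), dims)

# convolution kernels store all temporal taps along the input-channel axis:
# input channels are the channel-concatenation of (current frame, 1 frame
# back, ...), so a causal 3D convolution is one 2D convolution of the
# time-shift-augmented input
init_conv <- function(k, cin, cout, taps = 1L) {
  sd <- 1 / sqrt(k * k * cin * taps)
  rand_arr(c(k, k, cin * taps, cout), sd)
}

init_cell_params <- function(config, cf) {
  ch <- config$cell_channels
  b <- numeric(4L * ch)
  b[(ch + 1L):(2L * ch)] <- 1 # forget-gate bias
  # Wx mixes [Hf, Hm, other cells' hidden] (channel-concatenated) by 1x1
  # convolution: block-wise identical to separate 1x1 convolutions summed
  cin_mix <- cf + config$mod_hidden + (config$cells - 1L) * ch
  common <- list(Wx = init_conv(1L, cin_mix, ch), b = b)
  if (config$variant == "convlstm") {
    # gate convolutions of [X, H_prev] concatenated
    c(common, list(Wg = init_conv(3L, 2L * ch, 4L * ch)))
  } else {
    c(common, list(Wzc = init_conv(3L, 2L * ch, ch),
                   Wq = init_conv(1L, ch, ch), Wk = init_conv(1L, ch, ch),
                   Wv = init_conv(1L, ch, ch),
                   Wg = init_conv(1L, 2L * ch, 4L * ch)))
  }
}

init_head_params <- function(config, n_neurons) {
  m <- config$mod_hidden
  ni <- mod_inputs(config)
  bmod <- numeric(4L * m)
  bmod[(m + 1L):(2L * m)] <- 1
  ff <- list()
  cin <- 1L
  for (bk in seq_len(config$ff_blocks)) {
    g <- config$ff_growth
    ff[[bk]] <- list(
      layer1 = list(W = init_conv(3L, cin, g, config$ff_kt), b = numeric(g)),
      layer2 = list(W = init_conv(3L, cin + g, g, config$ff_kt), b = numeric(g)))
    # dense connections: each layer sees the block input plus prior layers
    cin <- cin + 2L * g
  }
  cf <- cin + if (config$spatial_grid) 2L else 0L
  C <- config$cells * config$cell_channels
  list(
    modulation = list(Wx = matrix(stats::rnorm(4 * m * ni, sd = 1 / sqrt(ni + m)), 4 * m, ni),
                      Wh = matrix(stats::rnorm(4 * m * m, sd = 1 / sqrt(ni + m)), 4 * m, m),
                      b = bmod),
    ff = ff,
    cells = lapply(seq_len(config$cells), function(i) init_cell_params(config, cf)),
    # small random feature weights: a zero readout would block gradient
    # flow into the core at the start of training
    readout = list(w = matrix(stats::rnorm(n_neurons * C, sd = 0.1), n_neurons, C),
                   b = numeric(n_neurons)))
}

#' Initialize an encoder model
#'
#' Builds retinal rays, the pupil MLP (final layer zero, so the initial gaze
#' correction is the identity), per-head modulation/core/readout parameters
#' and the shared readout position distribution (means at the feature-map
#' centre, isotropic s.d. `readout_sd_init` of the map extent).
#'
#' @param config An [encoder_config()].
#' @param n_neurons Number of readout neurons.
#' @param mon A [monitor_geometry()] (fixed; the calibrated physical setup).
#' @param seed RNG seed for parameter initialization.
#' @return A list of class `encoder_model`.
#' @export
encoder_init <- function(config, n_neurons, mon = monitor_geometry(), seed = 1L) {
  spec <- retinal_grid_spec(config$grid_height, config$grid_width, config$theta_max_deg)
  rays <- build_retinal_rays(spec)
  rays_mat <- matrix(rays$directions, spec$height * spec$width, 3)
  params <- with_preserved_seed(seed, {
    sd0 <- config$readout_sd_init * 2 # normalized coordinate extent is 2
    list(
      perspective = unclass(pupil_mlp_params(config$mlp_hidden, "calibrated",
                                             seed = seed + 7L)),
      readout_pos = list(mu = matrix(0, n_neurons, 2),
                         L = cbind(rep(sd0, n_neurons), 0, sd0)),
      heads = lapply(seq_len(config$heads), function(h) init_head_params(config, n_neurons)))
  })
  structure(list(config = config, mon = mon, grid_spec = spec,
                 rays_mat = rays_mat, grid_dim = c(spec$height, spec$width),
                 core_hw = core_map_dim(config), n_neurons = as.integer(n_neurons),
                 params = params,
                 norm = list(pupil_mean = c(0, 0), pupil_sd = c(1, 1),
                             behav_mean = numeric(3), behav_sd = rep(1, 3)),
                 train_stats = NULL),
            class = "encoder_model")
}

#' @export
print.encoder_model <- function(x, ...) {
  cat(sprintf("<encoder_model: %s, %d heads, core %d x %d ch on %d x %d map, %d neurons, %d parameters>\n",
              x$config$variant, x$config$heads, x$config$cells,
              x$config$cell_channels, x$core_hw[1], x$core_hw[2], x$n_neurons,
              count_parameters(x)))
  invisible(x)
}

## ---- parameter plumbing ----------------------------------------------------

# depth-first flatten of a nested list of numeric arrays; returns leaves and
# their paths ("heads.1.ff.2.layer1.W.1" style)
flatten_params <- function(x, path = character(0)) {
  if (is.numeric(x)) {
    out <- list(list(path = paste(path, collapse = "."), value = x))
    return(out)
  }
  out <- list()
  for (i in seq_along(x)) {
    nm <- if (!is.null(names(x)) && nzchar(names(x)[i])) names(x)[i] else as.character(i)
    out <- c(out, flatten_params(x[[i]], c(path, nm)))
  }
  out
}

#' Total parameter count of a model
#' @param model An `encoder_model`.
#' @return Integer number of scalar parameters.
#' @export
count_parameters <- function(model) {
  sum(vapply(flatten_params(model$params), function(l) length(l$value), 0))
}

# wrap every numeric leaf as an ag tensor; trainable leaves become graph
# parameters. `trainable` is a predicate over the dotted path.
wrap_params <- function(x, graph, trainable = function(path) TRUE, path = character(0)) {
  if (is.numeric(x)) {
    p <- paste(path, collapse = ".")
    if (!is.null(graph) && isTRUE(trainable(p))) return(ag_param(x, graph))
    return(ag_tensor(x))
  }
  out <- x
  for (i in seq_along(x)) {
    nm <- if (!is.null(names(x)) && nzchar(names(x)[i])) names(x)[i] else as.character(i)
    out[[i]] <- wrap_params(x[[i]], graph, trainable, c(path, nm))
  }
  out
}

unwrap_params <- function(x) {
  if (is_ag(x)) return(x$value)
  if (is.list(x)) return(lapply(x, unwrap_params))
  x
}

collect_tensors <- function(x) {
  if (is_ag(x)) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, collect_tensors)))
  list()
}

## ---- module steps ----------------------------------------------------------

# one LSTM cell update (gate order i, f, g, o); u is a constant [ni, 1]
# column, state a list(h, c) of [m, 1] tensors (or numerics)
lstm_step <- function(u, state, p) {
  lstm_step_preproj(ag_matmul(p$Wx, u), state, p)
}

# variant taking the already-projected input column Wx u  [4m, 1]
lstm_step_preproj <- function(xz, state, p) {
  z <- ag_add(ag_add(xz, ag_matmul(p$Wh, state$h)),
              ag_reshape(p$b, c(length(ag_val(p$b)), 1)))
  m <- nrow(ag_val(z)) %/% 4L
  i <- ag_sigmoid(ag_rows(z, 1:m))
  f <- ag_sigmoid(ag_rows(z, (m + 1L):(2L * m)))
  g <- ag_tanh(ag_rows(z, (2L * m + 1L):(3L * m)))
  o <- ag_sigmoid(ag_rows(z, (3L * m + 1L):(4L * m)))
  c_new <- ag_add(ag_mul(f, state$c), ag_mul(i, g))
  h_new <- ag_mul(o, ag_tanh(c_new))
  list(h = h_new, c = c_new)
}

#' One modulation-LSTM step
#'
#' Standard LSTM cell over the behavioural inputs (treadmill speed, pupil
#' diameter, and for the Conv-LSTM variant its derivative); the hidden
#' vector is tiled across space into modulation feature maps by
#' [tile_modulation()]. With all-zero parameters and zero state the update
#' gives exactly h = sigma(0) * tanh(sigma(0) * tanh(0)) = 0.
#'
#' @param behaviour_t Numeric behaviour vector at time t.
#' @param state List with `h`, `c` (numeric vectors) or NULL for zeros.
#' @param params List with `Wx` (`4m x ni`), `Wh` (`4m x m`), `b` (`4m`).
#' @return List with `h`, `c` numeric vectors.
#' @export
modulation_step <- function(behaviour_t, state, params) {
  if (any(!is.finite(behaviour_t))) stop("non-finite behaviour input", call. = FALSE)
  m <- length(params$b) %/% 4L
  if (is.null(state)) state <- list(h = matrix(0, m, 1), c = matrix(0, m, 1))
  st <- list(h = matrix(as.numeric(ag_val(state$h)), m, 1),
             c = matrix(as.numeric(ag_val(state$c)), m, 1))
  out <- lstm_step(matrix(behaviour_t, ncol = 1), st, params)
  list(h = as.numeric(ag_val(out$h)), c = as.numeric(ag_val(out$c)))
}

#' Tile a modulation hidden vector into feature maps
#' @param h Length-C hidden vector.
#' @param height,width Spatial size of the core feature maps.
#' @return `[height, width, C]` array with the identical vector at every
#'   spatial position.
#' @export
tile_modulation <- function(h, height, width) {
  ag_val(ag_tile_hw(h, height, width))
}

# one causal 3D-convolution layer on a flat clip matrix: channel-concat the
# temporal shifts, then a single 2D convolution over all frames
causal_conv3d_flat <- function(x, W, b, act, H, Wd, T, kt, dil = 1L) {
  hw <- H * Wd
  xin <- if (kt == 1L) x else {
    ag_cbind(c(list(x), lapply(seq_len(kt - 1L) * dil, function(s) {
      ag_tshift_flat(x, hw, T, min(s, T - 1L))
    })))
  }
  act(ag_conv2d_flat(xin, W, b, H, Wd, T))
}

# DenseNet feedforward over a flat clip matrix [H*W*T, 1]
feedforward_flat <- function(x, ffp, config, H, Wd, T) {
  act <- if (config$variant == "convlstm") ag_elu else ag_gelu
  kt <- config$ff_kt
  for (bk in seq_len(config$ff_blocks)) {
    bp <- ffp[[bk]]
    l1 <- causal_conv3d_flat(x, bp$layer1$W, bp$layer1$b, act, H, Wd, T, kt,
                             config$ff_t_dilation)
    cat1 <- ag_cbind(list(x, l1))
    l2 <- causal_conv3d_flat(cat1, bp$layer2$W, bp$layer2$b, act, H, Wd, T, kt,
                             config$ff_t_dilation)
    x <- ag_pool2_flat(ag_cbind(list(cat1, l2)), H, Wd, T)
    H <- H %/% 2L; Wd <- Wd %/% 2L
  }
  x
}

#' Causal DenseNet feedforward features for a clip
#'
#' Runs the three-block causal 3D-convolution DenseNet on a perspective
#' clip. Output at time t depends only on frames at times <= t (left-side
#' temporal padding); spatial size is halved after each block.
#'
#' @param clip `[T, h, w]` array of retinal activations.
#' @param head_params One element of `model$params$heads` (or compatible).
#' @param config The [encoder_config()].
#' @return `[T, h', w', C_f]` array of feedforward features.
#' @export
feedforward <- function(clip, head_params, config) {
  if (length(dim(clip)) != 3 || dim(clip)[1] < 1) stop("need a [T,h,w] clip", call. = FALSE)
  T <- dim(clip)[1]
  h <- dim(clip)[2]; w <- dim(clip)[3]
  x <- matrix(aperm(clip, c(2, 3, 1)), h * w * T, 1)
  out <- ag_val(feedforward_flat(ag_tensor(x), head_params$ff, config, h, w, T))
  d2 <- core_map_dim_from(h, w, config$ff_blocks)
  aperm(array(out, c(d2[1], d2[2], T, ncol(out))), c(3, 1, 2, 4))
}

core_map_dim_from <- function(h, w, blocks) {
  for (b in seq_len(blocks)) { h <- h %/% 2L; w <- w %/% 2L }
  c(h, w)
}

gate_split <- function(z4, ch) {
  list(i = ag_sigmoid(ag_slice_c(z4, 1L, ch)),
       f = ag_sigmoid(ag_slice_c(z4, ch + 1L, 2L * ch)),
       g = ag_tanh(ag_slice_c(z4, 2L * ch + 1L, 3L * ch)),
       o = ag_sigmoid(ag_slice_c(z4, 3L * ch + 1L, 4L * ch)))
}

convlstm_cell_step <- function(Hf, Hm, prev_h, prev_c, cell_idx, cp, ch) {
  x <- ag_conv2d(ag_concat_c(c(list(Hf, Hm), prev_h[-cell_idx])), cp$Wx)
  z4 <- ag_conv2d(ag_concat_c(list(x, prev_h[[cell_idx]])), cp$Wg, cp$b)
  gates <- gate_split(z4, ch)
  c_new <- ag_add(ag_mul(gates$f, prev_c[[cell_idx]]), ag_mul(gates$i, gates$g))
  h_new <- ag_mul(gates$o, ag_tanh(c_new))
  list(h = h_new, c = c_new)
}

# scaled dot-product attention over spatial tokens of Z
spatial_attention <- function(Z, cp) {
  d <- dim(ag_val(Z))
  ch <- d[3]
  q <- ag_reshape(ag_conv2d(Z, cp$Wq), c(d[1] * d[2], ch))
  k <- ag_reshape(ag_conv2d(Z, cp$Wk), c(d[1] * d[2], ch))
  v <- ag_reshape(ag_conv2d(Z, cp$Wv), c(d[1] * d[2], ch))
  scores <- ag_scale(ag_matmul(q, ag_t(k)), 1 / sqrt(ch))
  att <- ag_matmul(ag_softmax_rows(scores), v)
  ag_reshape(att, d)
}

cvtlstm_cell_step <- function(Hf, Hm, prev_h, prev_c, cell_idx, cp, ch) {
  x <- ag_conv2d(ag_concat_c(c(list(Hf, Hm), prev_h[-cell_idx])), cp$Wx)
  z <- ag_conv2d(ag_concat_c(list(x, prev_h[[cell_idx]])), cp$Wzc)
  a <- spatial_attention(z, cp)
  z4 <- ag_conv2d(ag_concat_c(list(a, z)), cp$Wg, cp$b)
  gates <- gate_split(z4, ch)
  c_new <- ag_add(ag_mul(gates$f, prev_c[[cell_idx]]), ag_mul(gates$i, gates$g))
  h_new <- ag_mul(gates$o, ag_tanh(c_new))
  list(h = h_new, c = c_new)
}

#' One Conv-LSTM core step
#'
#' Computes, for every recurrent cell, the input map
#' `X = W1*Hf + W1*Hm + sum_{c'} W1*H_prev[c']` (1x1 convolutions; the sum
#' runs over the other cells), the four gates from 3x3 convolutions of X and
#' the cell's own previous hidden map, and the state update
#' `C = F.C_prev + I.G`, `H = O.tanh(C)`.
#'
#' @param Hf `[h,w,Cf]` feedforward features at time t.
#' @param Hm `[h,w,Cm]` tiled modulation features at time t.
#' @param states List with `h`, `c`: lists (one `[h,w,ch]` array per cell);
#'   NULL for zero initial state.
#' @param cells_params `model$params$heads[[k]]$cells`.
#' @param config The [encoder_config()] (`variant` selects the update rule).
#' @return Updated `states` (numeric arrays).
#' @export
convlstm_step <- function(Hf, Hm, states, cells_params, config) {
  ch <- config$cell_channels
  d <- dim(Hf)[1:2]
  if (is.null(states)) {
    zero <- array(0, c(d, ch))
    states <- list(h = lapply(seq_len(config$cells), function(i) zero),
                   c = lapply(seq_len(config$cells), function(i) zero))
  }
  prev_h <- lapply(states$h, ag_tensor)
  prev_c <- lapply(states$c, ag_tensor)
  Hf_t <- ag_tensor(Hf); Hm_t <- ag_tensor(Hm)
  step_fn <- if (config$variant == "convlstm") convlstm_cell_step else cvtlstm_cell_step
  out_h <- list(); out_c <- list()
  for (ci in seq_len(config$cells)) {
    st <- step_fn(Hf_t, Hm_t, prev_h, prev_c, ci, cells_params[[ci]], ch)
    out_h[[ci]] <- ag_val(st$h)
    out_c[[ci]] <- ag_val(st$c)
  }
  list(h = out_h, c = out_c)
}

#' One CvT-LSTM core step
#'
#' The convolutional-transformer variant: `Z = W3*X + W3*H_prev`, spatial
#' tokens `Q, K, V = W1*Z`, scaled dot-product attention over all tokens,
#' and gates from 1x1 convolutions of the attention output and Z. Errors if
#' the model is not configured with `variant = "cvtlstm"`.
#'
#' @inheritParams convlstm_step
#' @return Updated `states` (numeric arrays).
#' @export
cvt_lstm_step <- function(Hf, Hm, states, cells_params, config) {
  if (config$variant != "cvtlstm") {
    stop("cvt_lstm_step requires an encoder configured with variant = 'cvtlstm'",
         call. = FALSE)
  }
  convlstm_step(Hf, Hm, states, cells_params, config)
}

#' Concatenate recurrent cell hidden maps into the core output
#' @param states States list from [convlstm_step()].
#' @return `[h, w, C]` array, `C = cells x cell_channels`.
#' @export
core_output <- function(states) {
  ag_val(ag_concat_c(lapply(states$h, ag_tensor)))
}

#' Factorized readout responses from a core feature map
#'
#' Bilinearly interpolates the core output at each neuron's readout position
#' and maps the feature vector through `r = exp(h . w + b)`. In `"train"`
#' mode positions are sampled from the learned Gaussian
#' `p ~ N(mu, LL^T)` via the reparameterization trick (seeded); in `"eval"`
#' mode the mean `mu` is used.
#'
#' @param H `[h, w, C]` core output map.
#' @param pos List with `mu` (`N x 2`, normalized `[-1,1]` coordinates) and
#'   `L` (`N x 3` Cholesky factors `(l11, l21, l22)` of the position
#'   covariance).
#' @param weights List with `w` (`N x C`) and `b` (`N`).
#' @param mode `"eval"` or `"train"`.
#' @param seed RNG seed for the train-mode position sample.
#' @return Length-N vector of strictly positive responses.
#' @export
readout_response <- function(H, pos, weights, mode = c("eval", "train"), seed = 1L) {
  mode <- match.arg(mode)
  N <- nrow(pos$mu)
  p <- if (mode == "eval") pos$mu else {
    eps <- with_preserved_seed(seed, matrix(stats::rnorm(2 * N), N, 2))
    reparam_positions_num(pos$mu, pos$L, eps)
  }
  feats <- ag_val(ag_bilinear_read(ag_tensor(H), ag_tensor(p)))
  as.numeric(exp(rowSums(feats * weights$w) + weights$b))
}

reparam_positions_num <- function(mu, L, eps) {
  cbind(mu[, 1] + L[, 1] * eps[, 1],
        mu[, 2] + L[, 2] * eps[, 1] + L[, 3] * eps[, 2])
}

# differentiable reparameterized positions: mu [N,2], L [N,3], eps [N,2] const
ag_reparam_positions <- function(mu, L, eps) {
  muv <- ag_val(mu); Lv <- ag_val(L)
  v <- reparam_positions_num(muv, Lv, eps)
  ag_op(v, list(mu, L), function(go) {
    gL <- cbind(go[, 1] * eps[, 1], go[, 2] * eps[, 1], go[, 2] * eps[, 2])
    list(go, gL)
  })
}

## ---- full forward ----------------------------------------------------------

standardize_behaviour <- function(model, behavior) {
  bm <- model$norm$behav_mean; bs <- model$norm$behav_sd
  B <- cbind((behavior$treadmill - bm[1]) / bs[1],
             (behavior$pupil - bm[2]) / bs[2],
             (behavior$pupil_d - bm[3]) / bs[3])
  if (mod_inputs(model$config) == 2L) B[, 1:2, drop = FALSE] else B
}

standardize_pupil <- function(model, pupil_xy) {
  sweep(sweep(pupil_xy, 2, model$norm$pupil_mean, "-"), 2, model$norm$pupil_sd, "/")
}

spatial_grid_maps <- function(h, w) {
  gx <- array(rep(seq(-1, 1, length.out = w), each = h), c(h, w, 1))
  gy <- array(rep(seq(-1, 1, length.out = h), times = w), c(h, w, 1))
  list(gx = gx, gy = gy)
}

#' Full encoder forward pass over one clip
#'
#' Runs perspective -> feedforward -> modulation -> recurrent core ->
#' readout for every head. The feedforward stage is evaluated time-batched
#' on flat clip matrices; the recurrent loop is sequential in time; the
#' readout is applied to the stacked core outputs. Used directly for
#' training and audits; [predict_responses()] is the high-level interface.
#'
#' @param model An `encoder_model`.
#' @param frames `[T, H, W]` stimulus frames (0-255).
#' @param behavior List with `treadmill`, `pupil`, `pupil_d` traces.
#' @param pupil_xy `T x 2` pupil-centre positions.
#' @param pt Parameter structure (possibly wrapped for training); defaults
#'   to the model's parameters.
#' @param mode `"eval"` (readout at the position mean) or `"train"`
#'   (positions sampled via `pos_eps`).
#' @param pos_eps Optional `N x 2` standard-normal draws for the
#'   reparameterized readout positions.
#' @param return_features Also return the first head's stacked core output.
#' @return List with `head_tensors` (per-head response tensors), `rates`
#'   (`T x N x heads` array) and optionally `core_stack`.
#' @export
encoder_forward <- function(model, frames, behavior, pupil_xy, pt = model$params,
                            mode = "eval", pos_eps = NULL, return_features = FALSE) {
  config <- model$config
  T <- dim(frames)[1]
  gh <- model$grid_dim[1]; gw <- model$grid_dim[2]
  hw_in <- gh * gw
  Bm <- standardize_behaviour(model, behavior)
  Pm <- standardize_pupil(model, pupil_xy)
  angles <- ag_pupil_to_rotation(Pm, pt$perspective)
  persp <- lapply(seq_len(T), function(t) {
    ag_reshape(ag_perspective_frame(frames[t, , ], ag_rows(angles, t),
                                    model$rays_mat, model$grid_dim, model$mon,
                                    fill = config$fill),
               c(hw_in, 1L))
  })
  # centre the retinal input so the background maps to zero drive
  persp_flat <- ag_add(ag_rbind(persp), -config$fill)
  pos <- if (mode == "train") {
    if (is.null(pos_eps)) pos_eps <- matrix(0, model$n_neurons, 2)
    ag_reparam_positions(pt$readout_pos$mu, pt$readout_pos$L, pos_eps)
  } else pt$readout_pos$mu
  ch <- config$cell_channels
  chw <- model$core_hw
  hw_core <- chw[1] * chw[2]
  grid_maps <- if (config$spatial_grid) spatial_grid_maps(chw[1], chw[2]) else NULL
  step_fn <- if (config$variant == "convlstm") convlstm_cell_step else cvtlstm_cell_step
  head_out <- vector("list", config$heads)
  rates <- array(0, c(T, model$n_neurons, config$heads))
  for (hd in seq_len(config$heads)) {
    hp <- pt$heads[[hd]]
    Hf_flat <- feedforward_flat(persp_flat, hp$ff, config, gh, gw, T)
    # per-frame feedforward maps for the recurrent loop
    cf <- ncol(ag_val(Hf_flat))
    Hf_list <- lapply(seq_len(T), function(t) {
      m <- ag_rows(Hf_flat, ((t - 1L) * hw_core + 1L):(t * hw_core))
      m <- ag_reshape(m, c(chw[1], chw[2], cf))
      if (config$spatial_grid) {
        ag_concat_c(list(m, ag_tensor(grid_maps$gx), ag_tensor(grid_maps$gy)))
      } else m
    })
    # modulation LSTM: input projection for the whole clip at once
    m <- config$mod_hidden
    xproj <- ag_matmul(Bm, ag_t(hp$modulation$Wx)) # [T, 4m]
    mstate <- list(h = ag_tensor(matrix(0, m, 1)), c = ag_tensor(matrix(0, m, 1)))
    zero_map <- ag_tensor(array(0, c(chw, ch)))
    prev_h <- lapply(seq_len(config$cells), function(i) zero_map)
    prev_c <- lapply(seq_len(config$cells), function(i) zero_map)
    core_flat <- vector("list", T)
    for (t in seq_len(T)) {
      mstate <- lstm_step_preproj(ag_t(ag_rows(xproj, t)), mstate, hp$modulation)
      Hm <- ag_tile_hw(mstate$h, chw[1], chw[2])
      new_h <- vector("list", config$cells); new_c <- vector("list", config$cells)
      for (ci in seq_len(config$cells)) {
        st <- step_fn(Hf_list[[t]], Hm, prev_h, prev_c, ci, hp$cells[[ci]], ch)
        new_h[[ci]] <- st$h; new_c[[ci]] <- st$c
      }
      prev_h <- new_h; prev_c <- new_c
      core_flat[[t]] <- ag_scale(ag_reshape(ag_concat_c(prev_h),
                                            c(hw_core, config$cells * ch)),
                                 config$feature_gain)
    }
    Hstack <- ag_rbind(core_flat)
    feats <- ag_bilinear_read_clip(Hstack, pos, chw[1], chw[2], T)
    r <- ag_readout_exp_clip(feats, hp$readout$w, hp$readout$b, T)
    head_out[[hd]] <- r
    rates[, , hd] <- matrix(ag_val(r), T, model$n_neurons)
    if (return_features && hd == 1L) core_stack <- ag_val(Hstack)
  }
  out <- list(head_tensors = head_out, rates = rates)
  if (return_features) out$core_stack <- core_stack
  out
}

#' Ensemble prediction from per-head responses
#'
#' Standardizes each head's log-responses with that head's per-neuron
#' training statistics, averages the z-scores across heads, de-standardizes
#' with the across-head mean statistics and exponentiates. Neurons whose
#' log-response s.d. is (near) zero in any head fall back to plain
#' log-response averaging.
#'
#' @param head_rates List over heads of `T x N` positive response matrices.
#' @param train_stats List over heads of lists with `mean`, `sd` (length-N
#'   log-response statistics from the training split); NULL averages
#'   unstandardized log-responses.
#' @return `T x N` matrix of ensembled responses (positive).
#' @export
ensemble_predict <- function(head_rates, train_stats = NULL) {
  H <- length(head_rates)
  logs <- lapply(head_rates, log)
  if (is.null(train_stats)) {
    return(exp(Reduce(`+`, logs) / H))
  }
  N <- ncol(head_rates[[1]])
  sds <- vapply(train_stats, function(s) s$sd, numeric(N))
  means <- vapply(train_stats, function(s) s$mean, numeric(N))
  ok <- apply(matrix(sds, ncol = H), 1, function(x) all(x > 1e-8))
  mbar <- rowMeans(matrix(means, ncol = H))
  sbar <- rowMeans(matrix(sds, ncol = H))
  z <- 0
  for (hd in seq_len(H)) {
    z <- z + sweep(sweep(logs[[hd]], 2, train_stats[[hd]]$mean, "-"), 2,
                   pmax(train_stats[[hd]]$sd, 1e-8), "/")
  }
  z <- z / H
  out <- exp(sweep(sweep(z, 2, sbar, "*"), 2, mbar, "+"))
  if (any(!ok)) {
    fallback <- exp(Reduce(`+`, logs) / H)
    out[, !ok] <- fallback[, !ok]
  }
  out
}

#' Predict responses for a stimulus/behaviour segment
#'
#' Runs every head in evaluation mode (readout at the position mean) and
#' combines heads with [ensemble_predict()] using the stored training
#' statistics.
#'
#' @param model A trained `encoder_model`.
#' @param frames `[T, H, W]` stimulus frames (monitor pixels, 0-255).
#' @param behavior List with `treadmill`, `pupil`, `pupil_d` traces; NULL
#'   for resting behaviour (all zeros).
#' @param pupil_xy `T x 2` pupil positions; NULL for the session mean.
#' @return `T x N` matrix of predicted responses.
#' @export
predict_responses <- function(model, frames, behavior = NULL, pupil_xy = NULL) {
  T <- dim(frames)[1]
  if (is.null(behavior)) {
    behavior <- list(treadmill = numeric(T), pupil = numeric(T), pupil_d = numeric(T))
    behavior$treadmill <- rep(model$norm$behav_mean[1], T)
    behavior$pupil <- rep(model$norm$behav_mean[2], T)
    behavior$pupil_d <- rep(model$norm$behav_mean[3], T)
  }
  if (is.null(pupil_xy)) {
    pupil_xy <- matrix(rep(model$norm$pupil_mean, each = T), T, 2)
  }
  out <- encoder_forward(model, frames, behavior, pupil_xy, mode = "eval")
  head_rates <- lapply(seq_len(model$config$heads), function(h) out$rates[, , h, drop = FALSE][, , 1])
  if (model$config$heads == 1L) {
    r <- head_rates[[1]]
    if (is.null(dim(r))) r <- matrix(r, T, model$n_neurons)
    return(r)
  }
  ensemble_predict(head_rates, model$train_stats)
}

#' Apply a function to every numeric parameter leaf
#' @param x Nested parameter list.
#' @param f Function applied to each numeric array.
#' @return The transformed structure.
#' @export
map_params <- function(x, f) {
  if (is.numeric(x)) return(f(x))
  if (is.list(x)) return(lapply(x, map_params, f = f))
  x
}
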