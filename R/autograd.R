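# Minimal reverse-mode automatic differentiation on dense R arrays.
#
# Tensors are environments holding a value, an accumulated gradient, the
# graph (tape) they were recorded on, and a backward closure. Operations
# constant-fold when no input requires a gradient, so the same forward code
# serves both training (with a tape) and inference (without one).

ag_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- vector("list", 256L)
  g$n <- 0L
  g
}

ag_tensor <- function(value, graph = NULL, parents = NULL, backward = NULL) {
  t <- new.env(parent = emptyenv())
  t$value <- value
  t$grad <- NULL
  t$graph <- graph
  t$parents <- parents
  t$backward <- backward
  class(t) <- "ag_tensor"
  if (!is.null(graph) && !is.null(backward)) {
    g_n <- graph$n + 1L
    if (length(graph$nodes) < g_n) length(graph$nodes) <- 2L * g_n
    graph$n <- g_n
    graph$nodes[[g_n]] <- t
  }
  t
}

is_ag <- function(x) is.environment(x)

ag_val <- function(x) if (is.environment(x)) x$value else x

# Leaf parameter: recorded grads but no backward.
ag_param <- function(value, graph) {
  t <- ag_tensor(value, graph = graph)
  t$grad <- NULL
  t
}

ag_graph_of <- function(...) {
  for (x in list(...)) {
    if (is.environment(x) && !is.null(x$graph)) return(x$graph)
  }
  NULL
}

# Record an op node. `backward` receives the upstream gradient and must
# return a list of gradients aligned with `parents` (NULL entries allowed).
ag_op <- function(value, parents, backward) {
  g <- NULL
  for (x in parents) {
    if (is.environment(x) && !is.null(x$graph)) { g <- x$graph; break }
  }
  if (is.null(g)) return(ag_tensor(value))
  ag_tensor(value, graph = g, parents = parents, backward = backward)
}

ag_accum <- function(t, g) {
  if (is.null(t) || !is_ag(t) || is.null(t$graph)) return(invisible(NULL))
  if (is.null(t$grad)) t$grad <- g else t$grad <- t$grad + g
  invisible(NULL)
}

# Reverse sweep from `loss` (any tensor; seeded with ones of its shape).
ag_backward <- function(loss, seed_grad = NULL) {
  stopifnot(is_ag(loss))
  g <- loss$graph
  if (is.null(g)) stop("loss is not attached to a graph")
  if (is.null(seed_grad)) {
    seed_grad <- ag_val(loss)
    seed_grad[] <- 1
  }
  loss$grad <- seed_grad
  for (i in seq.int(g$n, 1L)) {
    node <- g$nodes[[i]]
    if (is.null(node$grad)) next
    grads <- node$backward(node$grad)
    for (j in seq_along(node$parents)) {
      if (!is.null(grads[[j]])) ag_accum(node$parents[[j]], grads[[j]])
    }
    node$grad <- NULL # free
  }
  invisible(NULL)
}

## ---- elementwise ops -------------------------------------------------------

ag_add <- function(a, b) {
  v <- ag_val(a) + ag_val(b)
  ag_op(v, list(a, b), function(go) list(go, go))
}

ag_sub <- function(a, b) {
  v <- ag_val(a) - ag_val(b)
  ag_op(v, list(a, b), function(go) list(go, -go))
}

ag_mul <- function(a, b) {
  av <- ag_val(a); bv <- ag_val(b)
  ag_op(av * bv, list(a, b), function(go) list(go * bv, go * av))
}

# Multiply by a plain (non-differentiated) constant.
ag_scale <- function(a, k) {
  ag_op(ag_val(a) * k, list(a), function(go) list(go * k))
}

ag_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-ag_val(a)))
  ag_op(v, list(a), function(go) list(go * v * (1 - v)))
}

ag_tanh <- function(a) {
  v <- tanh(ag_val(a))
  ag_op(v, list(a), function(go) list(go * (1 - v^2)))
}

ag_exp <- function(a) {
  v <- exp(ag_val(a))
  ag_op(v, list(a), function(go) list(go * v))
}

ag_log <- function(a) {
  av <- ag_val(a)
  ag_op(log(av), list(a), function(go) list(go / av))
}

ag_elu <- function(a) {
  av <- ag_val(a)
  neg <- av <= 0
  ev <- exp(av * neg) # exp of non-positive part only (avoids overflow)
  v <- av
  v[neg] <- ev[neg] - 1
  ag_op(v, list(a), function(go) {
    d <- go
    d[neg] <- go[neg] * ev[neg]
    list(d)
  })
}

ag_gelu <- function(a) {
  av <- ag_val(a)
  # tanh approximation of the Gaussian error linear unit
  k <- sqrt(2 / pi)
  inner <- k * (av + 0.044715 * av^3)
  th <- tanh(inner)
  v <- 0.5 * av * (1 + th)
  ag_op(v, list(a), function(go) {
    dth <- (1 - th^2) * k * (1 + 3 * 0.044715 * av^2)
    list(go * (0.5 * (1 + th) + 0.5 * av * dth))
  })
}

ag_sum <- function(a) {
  av <- ag_val(a)
  ag_op(sum(av), list(a), function(go) {
    g <- av
    g[] <- as.numeric(go)
    list(g)
  })
}

## ---- shape ops -------------------------------------------------------------

ag_reshape <- function(a, dims) {
  av <- ag_val(a)
  od <- dim(av)
  v <- av
  dim(v) <- dims
  ag_op(v, list(a), function(go) {
    dim(go) <- od
    list(go)
  })
}

ag_rows <- function(a, idx) {
  av <- ag_val(a)
  v <- av[idx, , drop = FALSE]
  ag_op(v, list(a), function(go) {
    g <- av
    g[] <- 0
    g[idx, ] <- go
    list(g)
  })
}

# Concatenate [H,W,C_i] maps along channels.
ag_concat_c <- function(tensors) {
  vals <- lapply(tensors, ag_val)
  ncs <- vapply(vals, function(v) dim(v)[3], 0)
  v <- array(0, c(dim(vals[[1]])[1:2], sum(ncs)))
  at <- 0L
  for (x in vals) {
    nc <- dim(x)[3]
    v[, , at + seq_len(nc)] <- x
    at <- at + nc
  }
  ends <- cumsum(ncs)
  starts <- ends - ncs + 1L
  ag_op(v, tensors, function(go) {
    lapply(seq_along(tensors), function(i) {
      go[, , starts[i]:ends[i], drop = FALSE]
    })
  })
}

ag_slice_c <- function(a, from, to) {
  av <- ag_val(a)
  v <- av[, , from:to, drop = FALSE]
  ag_op(v, list(a), function(go) {
    g <- av
    g[] <- 0
    g[, , from:to] <- go
    list(g)
  })
}

## ---- linear algebra --------------------------------------------------------

ag_matmul <- function(a, b) {
  av <- ag_val(a); bv <- ag_val(b)
  ag_op(av %*% bv, list(a, b), function(go) {
    list(go %*% t(bv), crossprod(av, go))
  })
}

# Per-row dot products of two [N,C] matrices -> length-N vector.
ag_rowdot <- function(a, b) {
  av <- ag_val(a); bv <- ag_val(b)
  ag_op(rowSums(av * bv), list(a, b), function(go) {
    list(av * 0 + go * bv, bv * 0 + go * av)
  })
}

# Row-wise softmax of a matrix.
ag_softmax_rows <- function(a) {
  av <- ag_val(a)
  m <- apply(av, 1, max)
  e <- exp(av - m)
  v <- e / rowSums(e)
  ag_op(v, list(a), function(go) {
    dot <- rowSums(go * v)
    list(v * (go - dot))
  })
}

## ---- spatial ops -----------------------------------------------------------

.conv_cache <- new.env(parent = emptyenv())

conv2d_plan <- function(H, W, k, Cin) {
  key <- paste(H, W, k, Cin, sep = "_")
  pl <- .conv_cache[[key]]
  if (!is.null(pl)) return(pl)
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  pos_i <- rep(seq_len(H), times = W)
  pos_j <- rep(seq_len(W), each = H)
  offs <- as.matrix(expand.grid(di = 0:(k - 1L), dj = 0:(k - 1L)))
  IDX <- matrix(0L, H * W, k * k * Cin)
  col <- 0L
  for (cc in seq_len(Cin)) {
    chan_off <- (cc - 1L) * Hp * Wp
    for (m in seq_len(k * k)) {
      col <- col + 1L
      IDX[, col] <- (pos_i + offs[m, 1L]) + (pos_j + offs[m, 2L] - 1L) * Hp + chan_off
    }
  }
  pl <- list(p = p, Hp = Hp, Wp = Wp, IDX = IDX, offs = offs)
  .conv_cache[[key]] <- pl
  pl
}

# 2D "same" convolution (zero padding): x [H,W,Cin], w [k,k,Cin,Cout],
# optional bias b [Cout]. k odd.
ag_conv2d <- function(x, w, b = NULL) {
  xv <- ag_val(x); wv <- ag_val(w)
  d <- dim(xv)
  H <- d[1]; W <- d[2]; Cin <- d[3]
  k <- dim(wv)[1]
  Cout <- dim(wv)[4]
  wmat <- wv
  dim(wmat) <- c(k * k * Cin, Cout)
  if (k == 1L) {
    xmat <- xv
    dim(xmat) <- c(H * W, Cin)
    out <- xmat %*% wmat
    if (!is.null(b)) out <- sweep(out, 2, ag_val(b), "+")
    v <- out
    dim(v) <- c(H, W, Cout)
    parents <- list(x, w, b)
    return(ag_op(v, parents, function(go) {
      gom <- go
      dim(gom) <- c(H * W, Cout)
      gx <- gom %*% t(wmat)
      dim(gx) <- c(H, W, Cin)
      gw <- crossprod(xmat, gom)
      dim(gw) <- dim(wv)
      gb <- if (is.null(b)) NULL else colSums(gom)
      list(gx, gw, gb)
    }))
  }
  pl <- conv2d_plan(H, W, k, Cin)
  xp <- array(0, c(pl$Hp, pl$Wp, Cin))
  xp[pl$p + seq_len(H), pl$p + seq_len(W), ] <- xv
  X2 <- xp[pl$IDX]
  dim(X2) <- c(H * W, k * k * Cin)
  out <- X2 %*% wmat
  if (!is.null(b)) out <- sweep(out, 2, ag_val(b), "+")
  v <- out
  dim(v) <- c(H, W, Cout)
  parents <- list(x, w, b)
  ag_op(v, parents, function(go) {
    gom <- go
    dim(gom) <- c(H * W, Cout)
    gw <- crossprod(X2, gom)
    dim(gw) <- dim(wv)
    gX2 <- gom %*% t(wmat)
    # scatter-add per kernel offset: within one offset indices are unique,
    # so the accumulation is 9 shifted block additions instead of a rowsum
    gp <- array(0, c(pl$Hp, pl$Wp, Cin))
    kk <- k * k
    for (m in seq_len(kk)) {
      cols <- m + (seq_len(Cin) - 1L) * kk
      blk <- gX2[, cols]
      dim(blk) <- c(H, W, Cin)
      ri <- pl$offs[m, 1L] + seq_len(H)
      cj <- pl$offs[m, 2L] + seq_len(W)
      gp[ri, cj, ] <- gp[ri, cj, , drop = FALSE] + blk
    }
    gx <- gp[pl$p + seq_len(H), pl$p + seq_len(W), , drop = FALSE]
    gb <- if (is.null(b)) NULL else colSums(gom)
    list(gx, gw, gb)
  })
}

# 2x2 average pooling; trailing odd row/column is dropped.
ag_pool2 <- function(x) {
  xv <- ag_val(x)
  d <- dim(xv)
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  i1 <- seq_len(H2) * 2L - 1L
  j1 <- seq_len(W2) * 2L - 1L
  v <- (xv[i1, j1, , drop = FALSE] + xv[i1 + 1L, j1, , drop = FALSE] +
        xv[i1, j1 + 1L, , drop = FALSE] + xv[i1 + 1L, j1 + 1L, , drop = FALSE]) / 4
  ag_op(v, list(x), function(go) {
    g <- xv
    g[] <- 0
    q <- go / 4
    g[i1, j1, ] <- q
    g[i1 + 1L, j1, ] <- g[i1 + 1L, j1, , drop = FALSE] + q
    g[i1, j1 + 1L, ] <- g[i1, j1 + 1L, , drop = FALSE] + q
    g[i1 + 1L, j1 + 1L, ] <- g[i1 + 1L, j1 + 1L, , drop = FALSE] + q
    list(g)
  })
}

# Broadcast a length-C hidden vector (as [C,1] matrix or plain vector) to a
# [H,W,C] feature map.
ag_tile_hw <- function(h, H, W) {
  hv <- as.vector(ag_val(h))
  C <- length(hv)
  v <- array(rep(hv, each = H * W), c(H, W, C))
  ag_op(v, list(h), function(go) {
    g <- colSums(matrix(go, H * W, C))
    hv0 <- ag_val(h)
    dim(g) <- if (is.null(dim(hv0))) NULL else dim(hv0)
    list(g)
  })
}

# Bilinear interpolation of a feature map at per-neuron positions.
# H: [h,w,C]; pos: [N,2] in normalized coordinates [-1,1] (x = width axis,
# y = height axis, -1 maps to the first pixel centre, +1 to the last).
ag_bilinear_read <- function(Hmap, pos) {
  hv <- ag_val(Hmap)
  pv <- ag_val(pos)
  d <- dim(hv)
  h <- d[1]; w <- d[2]; C <- d[3]
  xf <- (pmin(pmax(pv[, 1], -1), 1) + 1) / 2 * (w - 1) # 0-based column
  yf <- (pmin(pmax(pv[, 2], -1), 1) + 1) / 2 * (h - 1) # 0-based row
  x0 <- pmin(floor(xf), w - 2); y0 <- pmin(floor(yf), h - 2)
  wx <- xf - x0; wy <- yf - y0
  N <- nrow(pv)
  hm <- matrix(hv, h * w, C)
  i00 <- (y0 + 1) + x0 * h
  i10 <- i00 + 1L         # +1 row
  i01 <- i00 + h          # +1 col
  i11 <- i01 + 1L
  w00 <- (1 - wy) * (1 - wx); w10 <- wy * (1 - wx)
  w01 <- (1 - wy) * wx;       w11 <- wy * wx
  v <- hm[i00, , drop = FALSE] * w00 + hm[i10, , drop = FALSE] * w10 +
       hm[i01, , drop = FALSE] * w01 + hm[i11, , drop = FALSE] * w11
  ag_op(v, list(Hmap, pos), function(go) {
    gH <- NULL
    if (is_ag(Hmap) && !is.null(Hmap$graph)) {
      idx <- c(i00, i10, i01, i11)
      wts <- c(w00, w10, w01, w11)
      gm <- matrix(0, h * w, C)
      contrib <- rbind(go * w00, go * w10, go * w01, go * w11)
      acc <- rowsum(contrib, group = idx, reorder = FALSE)
      gm[as.integer(rownames(acc)), ] <- gm[as.integer(rownames(acc)), ] + acc
      gH <- array(gm, c(h, w, C))
    }
    gP <- NULL
    if (is_ag(pos) && !is.null(pos$graph)) {
      # d value / d wx and d value / d wy, chain to normalized coords
      dvdx <- (hm[i01, , drop = FALSE] - hm[i00, , drop = FALSE]) * (1 - wy) +
              (hm[i11, , drop = FALSE] - hm[i10, , drop = FALSE]) * wy
      dvdy <- (hm[i10, , drop = FALSE] - hm[i00, , drop = FALSE]) * (1 - wx) +
              (hm[i11, , drop = FALSE] - hm[i01, , drop = FALSE]) * wx
      inb_x <- as.numeric(pv[, 1] > -1 & pv[, 1] < 1)
      inb_y <- as.numeric(pv[, 2] > -1 & pv[, 2] < 1)
      gP <- cbind(rowSums(go * dvdx) * (w - 1) / 2 * inb_x,
                  rowSums(go * dvdy) * (h - 1) / 2 * inb_y)
    }
    list(gH, gP)
  })
}

## ---- optimizer -------------------------------------------------------------

# Stochastic gradient descent with Nesterov momentum over a flat list of
# leaf parameter tensors.
sgd_state_new <- function(params) {
  lapply(params, function(p) {
    v <- ag_val(p)
    v[] <- 0
    v
  })
}

sgd_step <- function(params, state, lr, momentum = 0.9, clip_norm = Inf,
                     grad_scale = NULL) {
  grads <- lapply(params, function(p) p$grad)
  if (!is.null(grad_scale)) {
    for (i in seq_along(grads)) {
      if (!is.null(grads[[i]])) grads[[i]] <- grads[[i]] * grad_scale[i]
    }
  }
  tot <- sqrt(sum(vapply(grads, function(g) if (is.null(g)) 0 else sum(g^2), 0)))
  if (!is.finite(tot)) {
    # a non-finite gradient poisons the whole update; skip this step
    for (p in params) p$grad <- NULL
    return(state)
  }
  if (is.finite(clip_norm) && tot > clip_norm) {
    grads <- lapply(grads, function(g) if (is.null(g)) NULL else g * (clip_norm / tot))
  }
  for (i in seq_along(params)) {
    g <- grads[[i]]
    if (is.null(g)) next
    state[[i]] <- momentum * state[[i]] - lr * g
    params[[i]]$value <- params[[i]]$value + momentum * state[[i]] - lr * g
    params[[i]]$grad <- NULL
  }
  state
}

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## ---- time-batched (flat) ops ----------------------------------------------
# Flat representation of a clip of feature maps: a [H*W*T, C] matrix whose
# row index is pixel + (t-1)*H*W with pixel = i + (j-1)*H. The feedforward
# network is time-parallel, so convolutions over a whole clip become single
# GEMMs.

ag_cbind <- function(tensors) {
  vals <- lapply(tensors, ag_val)
  ncs <- vapply(vals, ncol, 0L)
  v <- do.call(cbind, vals)
  ends <- cumsum(ncs)
  starts <- ends - ncs + 1L
  ag_op(v, tensors, function(go) {
    lapply(seq_along(tensors), function(i) go[, starts[i]:ends[i], drop = FALSE])
  })
}

ag_rbind <- function(tensors) {
  vals <- lapply(tensors, ag_val)
  nrs <- vapply(vals, nrow, 0L)
  v <- do.call(rbind, vals)
  ends <- cumsum(nrs)
  starts <- ends - nrs + 1L
  ag_op(v, tensors, function(go) {
    lapply(seq_along(tensors), function(i) go[starts[i]:ends[i], , drop = FALSE])
  })
}

.conv_flat_cache <- new.env(parent = emptyenv())

conv2d_flat_plan <- function(H, W, T, k, Cin) {
  # gather indices grow with H*W*T*k*k*Cin; cache only training-sized clips
  # (long evaluation chunks would otherwise pin hundreds of MB per length)
  cacheable <- T <= 64L
  key <- paste(H, W, T, k, Cin, sep = "_")
  if (cacheable) {
    pl <- .conv_flat_cache[[key]]
    if (!is.null(pl)) return(pl)
  }
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  pos_i <- rep(seq_len(H), times = W)
  pos_j <- rep(seq_len(W), each = H)
  offs <- as.matrix(expand.grid(di = 0:(k - 1L), dj = 0:(k - 1L)))
  hw <- H * W
  # spatial gather index within one padded frame slab
  IDXs <- matrix(0L, hw, k * k)
  for (m in seq_len(k * k)) {
    IDXs[, m] <- (pos_i + offs[m, 1L]) + (pos_j + offs[m, 2L] - 1L) * Hp
  }
  slab <- Hp * Wp
  # full index over (pixel, t) rows and (m, c) columns for padded
  # array [Hp, Wp, T, Cin]
  rows_t <- rep((seq_len(T) - 1L) * slab, each = hw)
  IDX <- matrix(0L, hw * T, k * k * Cin)
  col <- 0L
  for (cc in seq_len(Cin)) {
    chan_off <- (cc - 1L) * slab * T
    for (m in seq_len(k * k)) {
      col <- col + 1L
      IDX[, col] <- rep(IDXs[, m], T) + rows_t + chan_off
    }
  }
  pl <- list(p = p, Hp = Hp, Wp = Wp, offs = offs, IDX = IDX)
  if (cacheable) .conv_flat_cache[[key]] <- pl
  pl
}

# "same" 2D convolution applied to every frame of a flat clip matrix
# x [H*W*T, Cin]; w [k,k,Cin,Cout]; b [Cout]
ag_conv2d_flat <- function(x, w, b, H, W, T) {
  xv <- ag_val(x); wv <- ag_val(w)
  Cin <- ncol(xv)
  k <- dim(wv)[1]
  Cout <- dim(wv)[4]
  wmat <- wv
  dim(wmat) <- c(k * k * Cin, Cout)
  if (k == 1L) {
    out <- xv %*% wmat
    if (!is.null(b)) out <- sweep(out, 2, ag_val(b), "+")
    return(ag_op(out, list(x, w, b), function(go) {
      gw <- crossprod(xv, go)
      dim(gw) <- dim(wv)
      list(go %*% t(wmat), gw, if (is.null(b)) NULL else colSums(go))
    }))
  }
  pl <- conv2d_flat_plan(H, W, T, k, Cin)
  xp <- array(0, c(pl$Hp, pl$Wp, T, Cin))
  xa <- xv
  dim(xa) <- c(H, W, T, Cin)
  xp[pl$p + seq_len(H), pl$p + seq_len(W), , ] <- xa
  X2 <- xp[pl$IDX]
  dim(X2) <- c(H * W * T, k * k * Cin)
  out <- X2 %*% wmat
  if (!is.null(b)) out <- sweep(out, 2, ag_val(b), "+")
  ag_op(out, list(x, w, b), function(go) {
    gw <- crossprod(X2, go)
    dim(gw) <- dim(wv)
    gX2 <- go %*% t(wmat)
    gp <- array(0, c(pl$Hp, pl$Wp, T, Cin))
    kk <- k * k
    for (m in seq_len(kk)) {
      cols <- m + (seq_len(Cin) - 1L) * kk
      blk <- gX2[, cols]
      dim(blk) <- c(H, W, T, Cin)
      ri <- pl$offs[m, 1L] + seq_len(H)
      cj <- pl$offs[m, 2L] + seq_len(W)
      gp[ri, cj, , ] <- gp[ri, cj, , , drop = FALSE] + blk
    }
    gx <- gp[pl$p + seq_len(H), pl$p + seq_len(W), , , drop = FALSE]
    dim(gx) <- c(H * W * T, Cin)
    gb <- if (is.null(b)) NULL else colSums(go)
    list(gx, gw, gb)
  })
}

.pool_flat_cache <- new.env(parent = emptyenv())

pool2_flat_plan <- function(H, W, T) {
  key <- paste(H, W, T, sep = "_")
  pl <- .pool_flat_cache[[key]]
  if (!is.null(pl)) return(pl)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  i2 <- rep(seq_len(H2), times = W2)
  j2 <- rep(seq_len(W2), each = H2)
  base <- lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)), function(o) {
    (2L * i2 - 1L + o[1]) + (2L * j2 - 2L + o[2]) * H
  })
  hw <- H * W
  toff <- rep((seq_len(T) - 1L) * hw, each = H2 * W2)
  idx <- lapply(base, function(bb) rep(bb, T) + toff)
  pl <- list(H2 = H2, W2 = W2, idx = idx, n_in = hw * T)
  .pool_flat_cache[[key]] <- pl
  pl
}

ag_pool2_flat <- function(x, H, W, T) {
  xv <- ag_val(x)
  pl <- pool2_flat_plan(H, W, T)
  v <- (xv[pl$idx[[1]], , drop = FALSE] + xv[pl$idx[[2]], , drop = FALSE] +
        xv[pl$idx[[3]], , drop = FALSE] + xv[pl$idx[[4]], , drop = FALSE]) / 4
  ag_op(v, list(x), function(go) {
    g <- matrix(0, pl$n_in, ncol(xv))
    q <- go / 4
    for (s in 1:4) g[pl$idx[[s]], ] <- g[pl$idx[[s]], , drop = FALSE] + q
    list(g)
  })
}

# shift a flat clip matrix by `shift` frames into the past (zero-fill front)
ag_tshift_flat <- function(x, hw, T, shift) {
  xv <- ag_val(x)
  C <- ncol(xv)
  n0 <- hw * shift
  v <- rbind(matrix(0, n0, C), xv[seq_len(hw * (T - shift)), , drop = FALSE])
  ag_op(v, list(x), function(go) {
    g <- matrix(0, hw * T, C)
    g[seq_len(hw * (T - shift)), ] <- go[(n0 + 1L):(hw * T), , drop = FALSE]
    list(g)
  })
}

# bilinear readout of a whole clip: Hstack [hw*T, C] (rows pixel + (t-1)*hw),
# pos [N,2] normalized; output [T*N, C] with rows t + (n-1)*T
ag_bilinear_read_clip <- function(Hstack, pos, h, w, T) {
  hv <- ag_val(Hstack)
  pv <- ag_val(pos)
  N <- nrow(pv)
  hw <- h * w
  xf <- (pmin(pmax(pv[, 1], -1), 1) + 1) / 2 * (w - 1)
  yf <- (pmin(pmax(pv[, 2], -1), 1) + 1) / 2 * (h - 1)
  x0 <- pmin(floor(xf), w - 2); y0 <- pmin(floor(yf), h - 2)
  wx <- xf - x0; wy <- yf - y0
  i00 <- (y0 + 1) + x0 * h
  toff <- rep.int((seq_len(T) - 1L) * hw, N)
  r00 <- rep(i00, each = T) + toff
  r10 <- r00 + 1L
  r01 <- r00 + h
  r11 <- r01 + 1L
  e <- function(z) rep(z, each = T)
  w00 <- e((1 - wy) * (1 - wx)); w10 <- e(wy * (1 - wx))
  w01 <- e((1 - wy) * wx);       w11 <- e(wy * wx)
  v <- hv[r00, , drop = FALSE] * w00 + hv[r10, , drop = FALSE] * w10 +
       hv[r01, , drop = FALSE] * w01 + hv[r11, , drop = FALSE] * w11
  ag_op(v, list(Hstack, pos), function(go) {
    gH <- NULL
    if (is.environment(Hstack) && !is.null(Hstack$graph)) {
      contrib <- rbind(go * w00, go * w10, go * w01, go * w11)
      idx <- c(r00, r10, r01, r11)
      acc <- rowsum(contrib, group = idx, reorder = FALSE)
      gH <- matrix(0, hw * T, ncol(hv))
      ids <- as.integer(rownames(acc))
      gH[ids, ] <- acc
    }
    gP <- NULL
    if (is.environment(pos) && !is.null(pos$graph)) {
      dvdx <- (hv[r01, , drop = FALSE] - hv[r00, , drop = FALSE]) * e(1 - wy) +
              (hv[r11, , drop = FALSE] - hv[r10, , drop = FALSE]) * e(wy)
      dvdy <- (hv[r10, , drop = FALSE] - hv[r00, , drop = FALSE]) * e(1 - wx) +
              (hv[r11, , drop = FALSE] - hv[r01, , drop = FALSE]) * e(wx)
      sx <- rowSums(go * dvdx); sy <- rowSums(go * dvdy)
      grp <- rep(seq_len(N), each = T)
      inb_x <- as.numeric(pv[, 1] > -1 & pv[, 1] < 1)
      inb_y <- as.numeric(pv[, 2] > -1 & pv[, 2] < 1)
      gP <- cbind(rowsum(sx, grp, reorder = FALSE) * (w - 1) / 2 * inb_x,
                  rowsum(sy, grp, reorder = FALSE) * (h - 1) / 2 * inb_y)
    }
    list(gH, gP)
  })
}

# per-neuron exponential readout over a clip: feats [T*N, C] (rows t-fastest),
# w [N,C], b [N]; returns exp responses [T*N]
ag_readout_exp_clip <- function(feats, w, b, T) {
  fv <- ag_val(feats); wv <- ag_val(w); bv <- ag_val(b)
  N <- nrow(wv)
  rep_idx <- rep(seq_len(N), each = T)
  wrep <- wv[rep_idx, , drop = FALSE]
  z <- rowSums(fv * wrep) + bv[rep_idx]
  live <- z < 30 # clamp the exponential to keep responses finite
  r <- exp(pmin(z, 30))
  ag_op(r, list(feats, w, b), function(go) {
    gr <- go * r * live
    gfeats <- gr * wrep
    gw <- rowsum(gr * fv, group = rep_idx, reorder = FALSE)
    gb <- as.numeric(rowsum(gr, group = rep_idx, reorder = FALSE))
    list(gfeats, gw, gb)
  })
}
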