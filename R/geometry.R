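# Perspective front-end: retinal ray construction on an azimuthal-equidistant
# grid, pupil-driven ocular rotation, monitor-plane intersection and bilinear
# resampling of the on-screen stimulus into retinal coordinates.

#' Retinal grid specification
#'
#' Defines a uniform Cartesian grid in the azimuthal-equidistant plane of the
#' retina. Grid point `(u, v)` maps to eccentricity
#' `theta = theta_max * sqrt(u^2 + v^2)` and azimuth `phi = atan2(v, u)`,
#' where `u` spans `[-1, 1]` along the width and `v` is scaled by the grid
#' aspect ratio so that grid pixels are square in the projection plane.
#'
#' @param height,width Number of grid rows / columns (each >= 2).
#' @param theta_max_deg Maximum eccentricity along the horizontal axis, in
#'   degrees (0 < theta_max <= 90).
#' @return An object of class `retinal_grid_spec`.
#' @export
retinal_grid_spec <- function(height = 37L, width = 65L, theta_max_deg = 60) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 2L || width < 2L) {
    stop("retinal grid must be at least 2 x 2", call. = FALSE)
  }
  if (!is.finite(theta_max_deg) || theta_max_deg <= 0 || theta_max_deg > 90) {
    stop("theta_max_deg must be in (0, 90]", call. = FALSE)
  }
  structure(list(height = height, width = width,
                 theta_max = theta_max_deg * pi / 180),
            class = "retinal_grid_spec")
}

#' Build unit retinal rays
#'
#' Maps every grid point through the azimuthal-equidistant projection onto the
#' unit sphere: `(theta, phi) -> (sin(theta)cos(phi), sin(theta)sin(phi),
#' cos(theta))`. The central ray points along `+z` (towards the monitor);
#' `+x` is rightward on the monitor and `+y` upward.
#'
#' @param spec A [retinal_grid_spec()].
#' @return A `ray_field`: list with `directions` (`height x width x 3` array of
#'   unit vectors) and the generating `spec`.
#' @export
build_retinal_rays <- function(spec) {
  stopifnot(inherits(spec, "retinal_grid_spec"))
  h <- spec$height; w <- spec$width
  u <- if (w > 1) seq(-1, 1, length.out = w) else 0
  aspect <- (h - 1) / (w - 1)
  v <- if (h > 1) seq(aspect, -aspect, length.out = h) else 0 # row 1 = top (+v up)
  U <- matrix(u, h, w, byrow = TRUE)
  V <- matrix(v, h, w)
  theta <- spec$theta_max * sqrt(U^2 + V^2)
  phi <- atan2(V, U)
  d <- array(0, c(h, w, 3))
  d[, , 1] <- sin(theta) * cos(phi)
  d[, , 2] <- sin(theta) * sin(phi)
  d[, , 3] <- cos(theta)
  structure(list(directions = d, spec = spec), class = "ray_field")
}

## ---- rotations -------------------------------------------------------------

rot_x <- function(a) matrix(c(1, 0, 0,
                              0, cos(a), sin(a),
                              0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a),
                              0, 1, 0,
                              sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0,
                              -sin(a), cos(a), 0,
                              0, 0, 1), 3, 3)
drot_x <- function(a) matrix(c(0, 0, 0,
                               0, -sin(a), cos(a),
                               0, -cos(a), -sin(a)), 3, 3)
drot_y <- function(a) matrix(c(-sin(a), 0, -cos(a),
                               0, 0, 0,
                               cos(a), 0, -sin(a)), 3, 3)
drot_z <- function(a) matrix(c(-sin(a), cos(a), 0,
                               -cos(a), -sin(a), 0,
                               0, 0, 0), 3, 3)

#' Compose the ocular rotation matrix `R_z(tz) R_y(ty) R_x(tx)`
#' @param rot Numeric length-3 vector `(theta_x, theta_y, theta_z)` in radians.
#' @return 3 x 3 rotation matrix.
#' @export
ocular_rotation_matrix <- function(rot) {
  stopifnot(length(rot) == 3, all(is.finite(rot)))
  rot_z(rot[3]) %*% rot_y(rot[2]) %*% rot_x(rot[1])
}

#' Rotate a ray field by ocular angles
#'
#' Applies `l_hat = R_z R_y R_x l` to every ray; norms are preserved.
#'
#' @param rays A `ray_field` from [build_retinal_rays()].
#' @param rot Length-3 rotation angles (radians).
#' @return A rotated `ray_field`.
#' @export
rotate_rays <- function(rays, rot) {
  stopifnot(inherits(rays, "ray_field"))
  R <- ocular_rotation_matrix(rot)
  d <- rays$directions
  dm <- matrix(d, prod(dim(d)[1:2]), 3)
  out <- dm %*% t(R)
  rays$directions <- array(out, dim(d))
  rays
}

## ---- monitor ---------------------------------------------------------------

#' Monitor geometry
#'
#' The monitor is a plane with pose `m0` (translation of its centre from the
#' eye, cm) and rotation angles `(tbar_x, tbar_y, tbar_z)`; its unit basis is
#' `[m_x m_y m_z] = R_z R_y R_x`. Defaults reproduce a 31.0 x 55.2 cm display
#' 15 cm in front of the eye, perpendicular at the nearest point.
#'
#' @param distance_cm Perpendicular eye-to-screen distance (used for the
#'   default `m0 = (0, 0, distance_cm)`).
#' @param width_cm,height_cm Physical screen size in cm.
#' @param width_px,height_px Pixel resolution of stimulus frames.
#' @param angles Length-3 plane rotation angles (radians).
#' @param m0 Optional explicit translation vector (overrides `distance_cm`).
#' @return An object of class `monitor_geometry`.
#' @export
monitor_geometry <- function(distance_cm = 15, width_cm = 55.2, height_cm = 31.0,
                             width_px = 64L, height_px = 36L,
                             angles = c(0, 0, 0), m0 = NULL) {
  if (is.null(m0)) m0 <- c(0, 0, distance_cm)
  if (width_cm <= 0 || height_cm <= 0) {
    stop("monitor physical size must be positive", call. = FALSE)
  }
  basis <- rot_z(angles[3]) %*% rot_y(angles[2]) %*% rot_x(angles[1])
  if (sum(m0 * basis[, 3]) <= 0) {
    stop("degenerate monitor pose: centre must lie in front of the eye (m0 . m_z > 0)",
         call. = FALSE)
  }
  structure(list(m0 = m0, angles = angles, basis = basis,
                 width_cm = width_cm, height_cm = height_cm,
                 width_px = as.integer(width_px), height_px = as.integer(height_px)),
            class = "monitor_geometry")
}

#' Intersect retinal rays with the monitor plane
#'
#' For each ray `l`, the intersection is `m = (m0 . m_z)/(l . m_z) l`, reported
#' as in-plane displacements `mx = (m - m0) . m_x`, `my = (m - m0) . m_y` from
#' the monitor centre (cm). Rays with `l . m_z <= 0` point away from the plane
#' and are flagged invalid.
#'
#' @param rays A `ray_field` (possibly rotated).
#' @param mon A [monitor_geometry()].
#' @return List with matrices `mx`, `my` (cm) and logical `valid`.
#' @export
project_to_monitor <- function(rays, mon) {
  stopifnot(inherits(rays, "ray_field"), inherits(mon, "monitor_geometry"))
  d <- rays$directions
  hw <- dim(d)[1:2]
  dm <- matrix(d, prod(hw), 3)
  mz <- mon$basis[, 3]; mx <- mon$basis[, 1]; my <- mon$basis[, 2]
  denom <- as.vector(dm %*% mz)
  valid <- denom > 1e-9
  num <- sum(mon$m0 * mz)
  scale <- ifelse(valid, num / denom, NA_real_)
  px <- dm * scale
  dx <- (px %*% mx) - sum(mon$m0 * mx)
  dy <- (px %*% my) - sum(mon$m0 * my)
  list(mx = matrix(dx, hw[1], hw[2]),
       my = matrix(dy, hw[1], hw[2]),
       valid = matrix(as.vector(valid), hw[1], hw[2]))
}

#' Angular resolution of the monitor
#'
#' Visual angle subtended by 1 cm of screen at on-screen distance `s` (cm)
#' from the nearest point: `(180/pi) * D / (D^2 + s^2)` degrees per cm, where
#' `D` is the perpendicular eye-to-screen distance. Strictly decreasing in
#' `s`; with the default 15 cm / 55.2 x 31.0 cm geometry it gives 3.8 deg/cm
#' at the nearest point and 0.7 deg/cm at the most remote corner.
#'
#' @param mon A [monitor_geometry()] (its `m0 . m_z` gives `D`) or a positive
#'   numeric distance in cm.
#' @param s On-screen distance from the nearest point, cm (vectorized).
#' @return Degrees per cm.
#' @export
angular_resolution <- function(mon, s = 0) {
  D <- if (inherits(mon, "monitor_geometry")) sum(mon$m0 * mon$basis[, 3]) else mon
  if (!is.finite(D) || D <= 0) stop("perpendicular distance must be positive", call. = FALSE)
  (180 / pi) * D / (D^2 + s^2)
}

#' Pixels per degree at the monitor centre
#'
#' Convenience conversion used by the stimulus generators: combines the
#' centre angular resolution with the pixel pitch.
#' @param mon A [monitor_geometry()].
#' @return Pixels per visual degree (horizontal pitch).
#' @export
pixels_per_degree <- function(mon) {
  cm_per_px <- mon$width_cm / mon$width_px
  1 / (angular_resolution(mon, 0) * cm_per_px)
}

## ---- sampling --------------------------------------------------------------

# cm displacements -> continuous 0-based pixel coordinates.
# Pixel j (0-based) has its centre at cm offset (j + 0.5 - width_px/2)*pitch;
# +my maps to decreasing row index (row 0 = top of the monitor).
monitor_cm_to_px <- function(mon, mx, my) {
  pitch_x <- mon$width_cm / mon$width_px
  pitch_y <- mon$height_cm / mon$height_px
  list(x = mx / pitch_x + mon$width_px / 2 - 0.5,
       y = mon$height_px / 2 - 0.5 - my / pitch_y)
}

#' Sample a stimulus frame at ray-monitor intersections
#'
#' Converts the cm displacement field to pixel coordinates and bilinearly
#' interpolates the frame at the four pixels surrounding each intersection.
#' Invalid rays and intersections falling outside the screen are filled with
#' `fill` (intensities are on the `[0, 1]` scale; frames stored 0-255 are
#' rescaled).
#'
#' @param frame Numeric matrix `height_px x width_px` (0-255 or already 0-1).
#' @param displ Displacement field from [project_to_monitor()].
#' @param mon A [monitor_geometry()].
#' @param fill Background value for off-screen samples (default mid-grey 0.5).
#' @return Matrix of retinal activations, same shape as the ray grid.
#' @export
sample_perspective <- function(frame, displ, mon, fill = 0.5) {
  if (!all(dim(frame) == c(mon$height_px, mon$width_px))) {
    stop("frame does not match the monitor pixel resolution", call. = FALSE)
  }
  frame <- frame_to_unit(frame)
  pc <- monitor_cm_to_px(mon, displ$mx, displ$my)
  bilinear_sample_clamped(frame, pc$x, pc$y, displ$valid, fill)
}

frame_to_unit <- function(frame) {
  if (max(frame, na.rm = TRUE) > 1 + 1e-9) frame / 255 else frame
}

# Bilinear interpolation with half-pixel edge hold; xf, yf are continuous
# 0-based coordinates, off-screen beyond the half-pixel border -> fill.
bilinear_sample_clamped <- function(img, xf, yf, valid, fill) {
  h <- nrow(img); w <- ncol(img)
  on_screen <- valid & xf >= -0.5 & xf <= w - 0.5 & yf >= -0.5 & yf <= h - 0.5
  on_screen[is.na(on_screen)] <- FALSE
  xc <- pmin(pmax(xf, 0), w - 1)
  yc <- pmin(pmax(yf, 0), h - 1)
  x0 <- pmin(floor(xc), w - 2); y0 <- pmin(floor(yc), h - 2)
  wx <- xc - x0; wy <- yc - y0
  i00 <- (y0 + 1) + x0 * h
  out <- img[i00] * (1 - wy) * (1 - wx) + img[i00 + 1] * wy * (1 - wx) +
         img[i00 + h] * (1 - wy) * wx + img[i00 + h + 1] * wy * wx
  out[!on_screen] <- fill
  dim(out) <- dim(xf)
  out
}

## ---- pupil MLP -------------------------------------------------------------

#' Parameters of the pupil-position to ocular-rotation perceptron
#'
#' A 3-layer perceptron (2 -> hidden -> hidden -> 3, tanh hidden units) maps
#' the standardized pupil-centre position onto the three ocular rotation
#' angles. The final layer is zero-initialized so that the initial gaze
#' correction is the identity (the calibrated physical setup).
#'
#' @param hidden Hidden layer width (default 8).
#' @param init `"zero"` (all weights zero) or `"calibrated"` (small random
#'   hidden weights, zero final layer).
#' @param seed RNG seed for `"calibrated"` initialization.
#' @return An object of class `pupil_mlp_params`.
#' @export
pupil_mlp_params <- function(hidden = 8L, init = c("calibrated", "zero"), seed = 1L) {
  init <- match.arg(init)
  hidden <- as.integer(hidden)
  rnd <- function(n, m) {
    if (init == "zero") matrix(0, n, m)
    else matrix(stats::rnorm(n * m, sd = 1 / sqrt(m)), n, m)
  }
  p <- with_preserved_seed(seed, {
    list(W1 = rnd(hidden, 2L), b1 = numeric(hidden),
         W2 = rnd(hidden, hidden), b2 = numeric(hidden),
         W3 = matrix(0, 3L, hidden), b3 = numeric(3L))
  })
  structure(p, class = "pupil_mlp_params")
}

#' Map pupil positions to ocular rotation angles
#'
#' @param pupil_xy Numeric length-2 vector or `T x 2` matrix of (standardized)
#'   pupil-centre coordinates.
#' @param params A [pupil_mlp_params()].
#' @return `T x 3` matrix of rotation angles (radians); a single input returns
#'   a `1 x 3` matrix.
#' @export
pupil_to_rotation <- function(pupil_xy, params) {
  if (is.null(dim(pupil_xy))) pupil_xy <- matrix(pupil_xy, nrow = 1)
  if (!all(is.finite(pupil_xy))) stop("pupil coordinates must be finite", call. = FALSE)
  h1 <- tanh(sweep(pupil_xy %*% t(params$W1), 2, params$b1, "+"))
  h2 <- tanh(sweep(h1 %*% t(params$W2), 2, params$b2, "+"))
  sweep(h2 %*% t(params$W3), 2, params$b3, "+")
}

# autograd version over wrapped parameter tensors; pupil_xy is a constant
# [T,2] matrix. Returns [T,3] tensor.
ag_pupil_to_rotation <- function(pupil_xy, pt) {
  h1 <- ag_tanh(ag_add(ag_matmul(pupil_xy, ag_t(pt$W1)), ag_row_broadcast(pt$b1, nrow(pupil_xy))))
  h2 <- ag_tanh(ag_add(ag_matmul(h1, ag_t(pt$W2)), ag_row_broadcast(pt$b2, nrow(pupil_xy))))
  ag_add(ag_matmul(h2, ag_t(pt$W3)), ag_row_broadcast(pt$b3, nrow(pupil_xy)))
}

# transpose op
ag_t <- function(a) {
  av <- ag_val(a)
  ag_op(t(av), list(a), function(go) list(t(go)))
}

# broadcast a length-C vector to an [n, C] matrix (same row repeated)
ag_row_broadcast <- function(b, n) {
  bv <- as.vector(ag_val(b))
  v <- matrix(bv, n, length(bv), byrow = TRUE)
  ag_op(v, list(b), function(go) list(colSums(go)))
}

## ---- differentiable perspective -------------------------------------------

# Differentiable perspective sampling for one frame. `angles` is a length-3
# tensor (or [1,3]); frame and geometry are constants. Gradients flow to the
# angles through the ray rotation, the plane intersection and the bilinear
# interpolation. Returns an [h, w, 1] tensor of retinal activations.
ag_perspective_frame <- function(frame, angles, rays_mat, grid_dim, mon, fill = 0.5) {
  av <- as.vector(ag_val(angles))
  Rx <- rot_x(av[1]); Ry <- rot_y(av[2]); Rz <- rot_z(av[3])
  R <- Rz %*% Ry %*% Rx
  dm <- rays_mat %*% t(R)
  mzv <- mon$basis[, 3]; mxv <- mon$basis[, 1]; myv <- mon$basis[, 2]
  denom <- as.vector(dm %*% mzv)
  valid <- denom > 1e-9
  num <- sum(mon$m0 * mzv)
  sc <- num / denom
  sc[!valid] <- 0
  mx <- sc * as.vector(dm %*% mxv) - sum(mon$m0 * mxv)
  my <- sc * as.vector(dm %*% myv) - sum(mon$m0 * myv)
  img <- frame_to_unit(frame)
  pc <- monitor_cm_to_px(mon, mx, my)
  h <- nrow(img); w <- ncol(img)
  xf <- pc$x; yf <- pc$y
  on_screen <- valid & xf >= -0.5 & xf <= w - 0.5 & yf >= -0.5 & yf <= h - 0.5
  xc <- pmin(pmax(xf * on_screen, 0), w - 1)
  yc <- pmin(pmax(yf * on_screen, 0), h - 1)
  x0 <- pmin(floor(xc), w - 2); y0 <- pmin(floor(yc), h - 2)
  wx <- xc - x0; wy <- yc - y0
  i00 <- (y0 + 1) + x0 * h
  v00 <- img[i00]; v10 <- img[i00 + 1]; v01 <- img[i00 + h]; v11 <- img[i00 + h + 1]
  out <- v00 * (1 - wy) * (1 - wx) + v10 * wy * (1 - wx) +
         v01 * (1 - wy) * wx + v11 * wy * wx
  out[!on_screen] <- fill
  value <- array(out, c(grid_dim[1], grid_dim[2], 1))
  if (!(is_ag(angles) && !is.null(angles$graph))) return(ag_tensor(value))

  pitch_x <- mon$width_cm / mon$width_px
  pitch_y <- mon$height_cm / mon$height_px
  ag_op(value, list(angles), function(go) {
    gov <- as.vector(go)
    # d(out)/d(pixel coords), zero where clamped/off-screen
    interior_x <- on_screen & xf > 0 & xf < w - 1
    interior_y <- on_screen & yf > 0 & yf < h - 1
    dvdx <- ((v01 - v00) * (1 - wy) + (v11 - v10) * wy) * interior_x
    dvdy <- ((v10 - v00) * (1 - wx) + (v11 - v01) * wx) * interior_y
    # pixel coords <- cm displacements
    g_mx <- gov * dvdx / pitch_x
    g_my <- gov * dvdy * (-1 / pitch_y)
    # displacements <- ray directions: d(mx)/dd = sc*mxv - (d.mxv)*sc/denom * mzv
    ddotx <- as.vector(dm %*% mxv); ddoty <- as.vector(dm %*% myv)
    common_x <- sc * g_mx; common_y <- sc * g_my
    denom_safe <- denom
    denom_safe[!valid] <- 1
    coef_mz <- -(common_x * ddotx + common_y * ddoty) / denom_safe
    gd <- outer(common_x, mxv) + outer(common_y, myv) + outer(coef_mz, mzv)
    gd[!on_screen, ] <- 0
    # ray directions <- angles
    dR1 <- Rz %*% Ry %*% drot_x(av[1])
    dR2 <- Rz %*% drot_y(av[2]) %*% Rx
    dR3 <- drot_z(av[3]) %*% Ry %*% Rx
    ga <- c(sum(gd * (rays_mat %*% t(dR1))),
            sum(gd * (rays_mat %*% t(dR2))),
            sum(gd * (rays_mat %*% t(dR3))))
    ga0 <- ag_val(angles)
    ga0[] <- ga
    list(ga0)
  })
}

## ---- seed helper -----------------------------------------------------------

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' seeded generators never perturb surrounding random draws.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
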