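# Temporal features: dense optical flow, flow histograms, motion energy,
# silhouette-center kinematics.

# Bilinear sampling of image `img` at (x + u, y + v), coordinates clamped
# to the frame.
bilinear_warp <- function(img, u, v) {
  H <- nrow(img); W <- ncol(img)
  x <- matrix(rep(seq_len(W) - 1, each = H), H) + u
  y <- matrix(rep(seq_len(H) - 1, times = W), H) + v
  x <- pmin(pmax(x, 0), W - 1)
  y <- pmin(pmax(y, 0), H - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
  fx <- x - x0; fy <- y - y0
  at <- function(yy, xx) img[cbind(as.vector(yy) + 1, as.vector(xx) + 1)]
  out <- (1 - fx) * (1 - fy) * at(y0, x0) + fx * (1 - fy) * at(y0, x1) +
         (1 - fx) * fy * at(y1, x0) + fx * fy * at(y1, x1)
  matrix(out, H, W)
}

hs_neighbor_avg <- function(m) {
  w1 <- 1 / 6; w2 <- 1 / 12
  w1 * (shift_replicate(m, 0, -1) + shift_replicate(m, 0, 1) +
        shift_replicate(m, -1, 0) + shift_replicate(m, 1, 0)) +
  w2 * (shift_replicate(m, -1, -1) + shift_replicate(m, -1, 1) +
        shift_replicate(m, 1, -1) + shift_replicate(m, 1, 1))
}

area_halve <- function(m) {
  A <- area_weights(nrow(m), max(1, nrow(m) %/% 2))
  B <- area_weights(ncol(m), max(1, ncol(m) %/% 2))
  A %*% m %*% t(B)
}

bilinear_resize <- function(m, H, W) {
  # separable linear interpolation used to upsample flow between levels
  xi <- (seq_len(W) - 1) * (ncol(m) - 1) / max(1, W - 1)
  yi <- (seq_len(H) - 1) * (nrow(m) - 1) / max(1, H - 1)
  x0 <- pmin(floor(xi) + 1, ncol(m)); x1 <- pmin(x0 + 1, ncol(m))
  y0 <- pmin(floor(yi) + 1, nrow(m)); y1 <- pmin(y0 + 1, nrow(m))
  fx <- xi - (x0 - 1); fy <- yi - (y0 - 1)
  rows <- m[y0, , drop = FALSE] * (1 - fy) + m[y1, , drop = FALSE] * fy
  rows[, x0, drop = FALSE] * rep(1 - fx, each = H) +
    rows[, x1, drop = FALSE] * rep(fx, each = H)
}

# Single-level Horn-Schunck iterations starting from (u, v).
hs_level <- function(f1, f2, u, v, alpha, n_iter) {
  f2w <- bilinear_warp(f2, u, v)
  favg <- (f1 + f2w) / 2
  Ix <- (shift_replicate(favg, 0, -1) - shift_replicate(favg, 0, 1)) / 2
  Iy <- (shift_replicate(favg, -1, 0) - shift_replicate(favg, 1, 0)) / 2
  It <- f2w - f1
  du <- matrix(0, nrow(f1), ncol(f1)); dv <- du
  denom_base <- alpha^2 + Ix^2 + Iy^2
  for (i in seq_len(n_iter)) {
    dub <- hs_neighbor_avg(du)
    dvb <- hs_neighbor_avg(dv)
    common <- (Ix * dub + Iy * dvb + It) / denom_base
    du <- dub - Ix * common
    dv <- dvb - Iy * common
  }
  list(u = u + du, v = v + dv)
}

#' Dense optical flow between two frames
#'
#' Estimates per-pixel displacement vectors `(u, v)` (px/frame) from
#' `frame_t` to `frame_t1`. The default estimator is a deterministic
#' coarse-to-fine Horn-Schunck scheme: an image pyramid is built by area
#' halving, flow is solved at the coarsest level and upsampled as the
#' initialization of the next, with incremental warping at each level.
#' Alternative estimators can be plugged in as a function
#' `f(frame_t, frame_t1) -> list(u, v)`.
#'
#' @param frame_t,frame_t1 Same-shape grayscale matrices.
#' @param estimator `"hs"` or a function as above.
#' @param alpha Horn-Schunck regularization weight (intensity units).
#' @param n_iter Iterations per pyramid level.
#' @param n_levels Pyramid depth; `NULL` chooses the deepest level whose
#'   smaller dimension is at least 16 px.
#' @return List with class `flow_field`: matrices `u`, `v`.
#' @export
compute_optical_flow <- function(frame_t, frame_t1, estimator = "hs",
                                 alpha = 6, n_iter = 120, n_levels = NULL) {
  if (!all(dim(frame_t) == dim(frame_t1))) stop("frame shape mismatch")
  if (is.function(estimator)) {
    fl <- estimator(frame_t, frame_t1)
    return(structure(list(u = fl$u, v = fl$v), class = "flow_field"))
  }
  if (!identical(estimator, "hs")) stop("unknown flow estimator: ", estimator)
  if (is.null(n_levels)) {
    n_levels <- max(1, floor(log2(min(dim(frame_t)) / 16)) + 1)
  }
  pyr1 <- list(frame_t); pyr2 <- list(frame_t1)
  for (l in seq_len(n_levels - 1)) {
    pyr1[[l + 1]] <- area_halve(pyr1[[l]])
    pyr2[[l + 1]] <- area_halve(pyr2[[l]])
  }
  u <- matrix(0, nrow(pyr1[[n_levels]]), ncol(pyr1[[n_levels]]))
  v <- u
  for (l in rev(seq_len(n_levels))) {
    f1 <- pyr1[[l]]; f2 <- pyr2[[l]]
    if (!all(dim(u) == dim(f1))) {
      scale_y <- nrow(f1) / nrow(u); scale_x <- ncol(f1) / ncol(u)
      u <- bilinear_resize(u, nrow(f1), ncol(f1)) * scale_x
      v <- bilinear_resize(v, nrow(f1), ncol(f1)) * scale_y
    }
    fl <- hs_level(f1, f2, u, v, alpha, n_iter)
    u <- fl$u; v <- fl$v
  }
  structure(list(u = u, v = v), class = "flow_field")
}

#' Histogram of oriented optical flow within a mask
#'
#' Flow vectors are binned exactly like image gradients in [compute_hog()]:
#' unsigned orientation over 180 degrees, 9 bins, magnitude-weighted, 8 x 8
#' px cells, 2 x 2 cell blocks with stride 1, block filtering by mask
#' center.
#'
#' @param flow A `flow_field`.
#' @param mask Logical matrix; defaults to the full frame.
#' @param cell_size Cell edge in pixels.
#' @return Matrix with columns `cx, cy, b1..b9`.
#' @export
compute_hof <- function(flow, mask = NULL, cell_size = 8) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(flow$u), ncol(flow$u))
  orientation_block_histograms(flow$u, flow$v, mask, cell_size = cell_size)
}

#' Motion energy of masked pixels
#'
#' The L2 norm of the flow vector at each pixel of the mask.
#'
#' @param flow A `flow_field`.
#' @param mask Logical matrix; defaults to the full frame.
#' @return Matrix with columns `x, y, e` (0-based coordinates).
#' @export
compute_motion_energy <- function(flow, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(flow$u), ncol(flow$u))
  pix <- which(mask, arr.ind = TRUE)
  e <- sqrt(flow$u[pix]^2 + flow$v[pix]^2)
  out <- cbind(x = pix[, 2] - 1, y = pix[, 1] - 1, e = e)
  out[order(out[, "x"], out[, "y"]), , drop = FALSE]
}

#' Silhouette-center kinematics
#'
#' The center of a silhouette is the mean of its pixel coordinates; the
#' displacement of that center between consecutive frames gives movement
#' direction (unit vector, undefined when the center does not move) and
#' speed in px/frame. Frames with an empty mask yield records flagged
#' missing, which are excluded when pooling.
#'
#' @param mask_sequence `H x W x n` logical array, `n >= 2`.
#' @return Data frame with one row per frame pair `(t, t+1)`, columns
#'   `t, cx, cy, dx, dy, speed, dir_x, dir_y, missing`.
#' @export
compute_center_kinematics <- function(mask_sequence) {
  n <- dim(mask_sequence)[3]
  if (n < 2) stop("kinematics needs at least 2 frames")
  centers <- t(vapply(seq_len(n), function(i) {
    pix <- which(mask_sequence[, , i], arr.ind = TRUE)
    if (nrow(pix) == 0) return(c(NA_real_, NA_real_))
    c(mean(pix[, 2] - 1), mean(pix[, 1] - 1))
  }, numeric(2)))
  t_idx <- seq_len(n - 1) - 1L
  dx <- centers[-1, 1] - centers[-n, 1]
  dy <- centers[-1, 2] - centers[-n, 2]
  speed <- sqrt(dx^2 + dy^2)
  dir_x <- ifelse(speed > 0, dx / speed, NA_real_)
  dir_y <- ifelse(speed > 0, dy / speed, NA_real_)
  data.frame(t = t_idx, cx = centers[-n, 1], cy = centers[-n, 2],
             dx = dx, dy = dy, speed = speed,
             dir_x = dir_x, dir_y = dir_y,
             missing = is.na(dx))
}
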