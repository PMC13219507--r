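# Per-frame spatial features: luminance, contrast, HOG, Canny edges,
# silhouette, silhouette size, Hu moments.

#' Low-level frame statistics
#'
#' Luminance of a frame is its mean grayscale intensity; contrast is the
#' population standard deviation of all pixel intensities.
#'
#' @param frame Numeric matrix, intensities in `[0, 255]`.
#' @return Scalar.
#' @export
compute_luminance <- function(frame) {
  if (length(frame) == 0) stop("empty frame")
  mean(frame)
}

#' @rdname compute_luminance
#' @export
compute_contrast <- function(frame) {
  if (length(frame) == 0) stop("empty frame")
  mu <- mean(frame)
  sqrt(mean((frame - mu)^2))
}

# Shift a matrix by (dr, dc) with edge replication.
shift_replicate <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) - dr, 1), h)
  ci <- pmin(pmax(seq_len(w) - dc, 1), w)
  m[ri, ci]
}

# Sobel gradients; x grows with columns, y with rows.
sobel_gradients <- function(frame) {
  sx <- function(m) shift_replicate(m, 0, -1) - shift_replicate(m, 0, 1)
  gx <- shift_replicate(frame, -1, -1) + 2 * shift_replicate(frame, 0, -1) +
        shift_replicate(frame, 1, -1) -
        shift_replicate(frame, -1, 1) - 2 * shift_replicate(frame, 0, 1) -
        shift_replicate(frame, 1, 1)
  gy <- shift_replicate(frame, -1, -1) + 2 * shift_replicate(frame, -1, 0) +
        shift_replicate(frame, -1, 1) -
        shift_replicate(frame, 1, -1) - 2 * shift_replicate(frame, 1, 0) -
        shift_replicate(frame, 1, 1)
  list(gx = gx, gy = gy)
}

# Shared cell/block orientation-histogram scheme for HOG and HOF.
# vx, vy: per-pixel vector field (image gradients or flow); orientation is
# unsigned (modulo 180 degrees), weights are vector magnitudes. Cells are
# cell_size x cell_size px (partial border cells dropped); blocks are 2x2
# cells with stride 1 cell; a block histogram is the mean of its 4 cell
# histograms, L2-normalized with a small guard so blank blocks stay zero.
# Blocks are kept when their center pixel falls inside the mask.
orientation_block_histograms <- function(vx, vy, mask, cell_size = 8,
                                         n_bins = 9) {
  H <- nrow(vx); W <- ncol(vx)
  n_cy <- H %/% cell_size
  n_cx <- W %/% cell_size
  if (n_cy < 2 || n_cx < 2) stop("frame too small for 2x2 cell blocks")
  hy <- n_cy * cell_size; wx <- n_cx * cell_size
  vx <- vx[seq_len(hy), seq_len(wx)]
  vy <- vy[seq_len(hy), seq_len(wx)]

  mag <- sqrt(vx^2 + vy^2)
  theta <- atan2(vy, vx) %% pi                    # unsigned, [0, pi)
  bin <- pmin(floor(theta / (pi / n_bins)), n_bins - 1)

  cell_row <- (row(vx) - 1) %/% cell_size
  cell_col <- (col(vx) - 1) %/% cell_size
  idx <- (cell_row * n_cx + cell_col) * n_bins + bin   # 0-based flat index
  acc <- rowsum(as.vector(mag), group = as.vector(idx))
  cell_hist <- matrix(0, n_cy * n_cx, n_bins)
  flat <- as.integer(rownames(acc))
  cell_hist[cbind(flat %/% n_bins + 1, flat %% n_bins + 1)] <- acc

  blocks <- list()
  centers <- list()
  k <- 0
  out_h <- matrix(0, (n_cy - 1) * (n_cx - 1), n_bins)
  out_c <- matrix(0, (n_cy - 1) * (n_cx - 1), 2)
  keep <- logical(nrow(out_h))
  for (by in 0:(n_cy - 2)) {
    for (bx in 0:(n_cx - 2)) {
      k <- k + 1
      cx <- bx * cell_size + cell_size   # 0-based block-center pixel
      cy <- by * cell_size + cell_size
      if (!mask[cy + 1, cx + 1]) next
      cells <- c(by * n_cx + bx, by * n_cx + bx + 1,
                 (by + 1) * n_cx + bx, (by + 1) * n_cx + bx + 1) + 1
      h <- colMeans(cell_hist[cells, , drop = FALSE])
      h <- h / (sqrt(sum(h^2)) + 1e-12)
      out_h[k, ] <- h
      out_c[k, ] <- c(cx, cy)
      keep[k] <- TRUE
    }
  }
  out <- cbind(out_c[keep, , drop = FALSE], out_h[keep, , drop = FALSE])
  colnames(out) <- c("cx", "cy", paste0("b", seq_len(n_bins)))
  out
}

#' Histogram of oriented gradients within a mask
#'
#' Sobel gradients are summarized into 9 orientation bins spanning an
#' unsigned 180 degrees, magnitude-weighted, over 8 x 8 px cells; blocks of
#' 2 x 2 cells (stride 1 cell) average their cell histograms and are
#' L2-normalized. Only blocks whose center pixel lies inside the mask are
#' returned, each as its center position plus 9 bin weights.
#'
#' @param frame Grayscale matrix.
#' @param mask Logical matrix of the same shape; defaults to the full frame.
#' @param cell_size Cell edge in pixels.
#' @return Matrix with columns `cx, cy, b1..b9`, one row per kept block
#'   (possibly 0 rows).
#' @export
compute_hog <- function(frame, mask = NULL, cell_size = 8) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(frame), ncol(frame))
  g <- sobel_gradients(frame)
  orientation_block_histograms(g$gx, g$gy, mask, cell_size = cell_size)
}

#' Canny edge pixels within a mask
#'
#' The frame is smoothed with a 3 x 3 Gaussian kernel, Sobel gradients are
#' taken, non-maximum suppression thins ridges along the quantized gradient
#' direction, and double-threshold hysteresis (low 50, high 200 on the
#' Sobel magnitude scale) keeps weak edge pixels only when 8-connected to a
#' strong one. Returned pixels are restricted to the mask.
#'
#' @param frame Grayscale matrix (`[0, 255]`).
#' @param mask Logical matrix; defaults to the full frame.
#' @param low,high Hysteresis thresholds.
#' @return Integer matrix with columns `x, y` (0-based), possibly 0 rows.
#' @export
compute_edges <- function(frame, mask = NULL, low = 50, high = 200) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(frame), ncol(frame))
  k <- c(1, 2, 1) / 4
  sm <- frame
  sm <- k[1] * shift_replicate(sm, -1, 0) + k[2] * sm + k[3] * shift_replicate(sm, 1, 0)
  sm <- k[1] * shift_replicate(sm, 0, -1) + k[2] * sm + k[3] * shift_replicate(sm, 0, 1)
  g <- sobel_gradients(sm)
  mag <- sqrt(g$gx^2 + g$gy^2)

  # quantize gradient direction to 0 / 45 / 90 / 135 degrees
  theta <- atan2(g$gy, g$gx) %% pi
  sector <- floor((theta + pi / 8) / (pi / 4)) %% 4
  off <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))   # (dy, dx) per sector
  nms <- matrix(FALSE, nrow(frame), ncol(frame))
  for (sct in 0:3) {
    d <- off[[sct + 1]]
    n1 <- shift_replicate(mag, d[1], d[2])
    n2 <- shift_replicate(mag, -d[1], -d[2])
    # asymmetric tie-break: a symmetric two-pixel ridge keeps one pixel
    nms <- nms | (sector == sct & mag >= n1 & mag > n2)
  }
  strong <- nms & mag >= high
  weak <- nms & mag >= low

  # hysteresis: flood weak pixels 8-connected to strong seeds
  H <- nrow(frame); W <- ncol(frame)
  keep <- strong
  queue <- which(strong)
  while (length(queue) > 0) {
    i <- queue[length(queue)]
    queue <- queue[-length(queue)]
    r <- (i - 1) %% H + 1
    cc <- (i - 1) %/% H + 1
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; c2 <- cc + dc
      if (rr < 1 || rr > H || c2 < 1 || c2 > W) next
      j <- (c2 - 1) * H + rr
      if (weak[j] && !keep[j]) {
        keep[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  pix <- which(keep & mask, arr.ind = TRUE)
  out <- cbind(x = pix[, 2] - 1L, y = pix[, 1] - 1L)
  out[order(out[, "x"], out[, "y"]), , drop = FALSE]
}

#' Silhouette pixels and silhouette size
#'
#' The silhouette is the set of pixels of a binary segmentation mask; its
#' size is their count.
#'
#' @param mask Logical matrix.
#' @return `compute_silhouette()`: integer matrix with columns `x, y`
#'   (0-based); `compute_silhouette_size()`: integer count.
#' @export
compute_silhouette <- function(mask) {
  pix <- which(mask, arr.ind = TRUE)
  out <- cbind(x = pix[, 2] - 1L, y = pix[, 1] - 1L)
  out[order(out[, "x"], out[, "y"]), , drop = FALSE]
}

#' @rdname compute_silhouette
#' @export
compute_silhouette_size <- function(mask) sum(mask)

#' Hu moment invariants of a silhouette
#'
#' The seven classical moment invariants of the binary mask, computed from
#' central moments normalized for scale. They are invariant to translation,
#' scale and rotation of the shape; the first six are also invariant to
#' reflection, while the seventh flips sign under mirroring.
#'
#' @param mask Logical matrix with at least one pixel set.
#' @return Numeric vector `h1..h7`.
#' @export
compute_hu_moments <- function(mask) {
  pix <- which(mask, arr.ind = TRUE)
  if (nrow(pix) == 0) stop("Hu moments are undefined for an empty mask")
  x <- pix[, 2] - 1
  y <- pix[, 1] - 1
  m00 <- length(x)
  xbar <- mean(x); ybar <- mean(y)
  cx <- x - xbar; cy <- y - ybar
  mu <- function(p, q) sum(cx^p * cy^q)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
          ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
        (3 * n21 - n03) * (n21 + n03) *
          (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
        4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
          ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
        (n30 - 3 * n12) * (n21 + n03) *
          (3 * (n30 + n12)^2 - (n21 + n03)^2)
  c(h1 = h1, h2 = h2, h3 = h3, h4 = h4, h5 = h5, h6 = h6, h7 = h7)
}
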