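# Rasterization helpers shared by the synthetic scene generator and by
# tests that need analytically known silhouettes.
#
# Convention used throughout the package: x grows rightwards, y grows
# downwards, origin at the top-left pixel, 0-based pixel coordinates.
# A mask is an H x W logical matrix with mask[y + 1, x + 1] addressing
# pixel (x, y); frames use the same indexing.

coord_grids <- function(height, width) {
  list(
    x = matrix(rep(seq_len(width) - 1, each = height), nrow = height),
    y = matrix(rep(seq_len(height) - 1, times = width), nrow = height)
  )
}

#' Rasterize simple shapes as binary masks
#'
#' Filled disks, axis-aligned ellipses, thick line segments (capsules) and
#' annular sectors (crescents) on the package's pixel raster. These are the
#' building blocks of the synthetic actor and are also convenient for
#' constructing silhouettes with known moments in tests.
#'
#' @param height,width Raster size in pixels.
#' @param cx,cy Center, 0-based pixel coordinates.
#' @param r Disk radius in pixels.
#' @return Logical `height` x `width` matrix.
#' @export
disk_mask <- function(height, width, cx, cy, r) {
  g <- coord_grids(height, width)
  (g$x - cx)^2 + (g$y - cy)^2 <= r^2
}

#' @rdname disk_mask
#' @param rx,ry Ellipse semi-axes in pixels.
#' @param angle Rotation of the ellipse, radians, counter-clockwise in the
#'   (x right, y down) frame.
#' @export
ellipse_mask <- function(height, width, cx, cy, rx, ry, angle = 0) {
  g <- coord_grids(height, width)
  dx <- g$x - cx
  dy <- g$y - cy
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  (u / rx)^2 + (v / ry)^2 <= 1
}

#' @rdname disk_mask
#' @param x0,y0,x1,y1 Segment endpoints, 0-based pixels.
#' @param w Segment thickness in pixels.
#' @export
segment_mask <- function(height, width, x0, y0, x1, y1, w) {
  g <- coord_grids(height, width)
  vx <- x1 - x0
  vy <- y1 - y0
  len2 <- vx^2 + vy^2
  if (len2 == 0) return(disk_mask(height, width, x0, y0, w / 2))
  t <- ((g$x - x0) * vx + (g$y - y0) * vy) / len2
  t <- pmin(pmax(t, 0), 1)
  px <- x0 + t * vx
  py <- y0 + t * vy
  (g$x - px)^2 + (g$y - py)^2 <= (w / 2)^2
}

#' @rdname disk_mask
#' @param r_in,r_out Inner and outer radius of the annulus.
#' @param dir Central angle (radians) of the angular window, measured from
#'   the +x axis towards +y.
#' @param half_angle Half-width of the angular window in radians.
#' @export
crescent_mask <- function(height, width, cx, cy, r_in, r_out, dir, half_angle) {
  g <- coord_grids(height, width)
  dx <- g$x - cx
  dy <- g$y - cy
  rr <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx)
  dang <- abs(((ang - dir + pi) %% (2 * pi)) - pi)
  rr >= r_in & rr <= r_out & dang <= half_angle
}

# 8-neighbour erosion; used to split a mask into boundary and interior.
erode8 <- function(mask) {
  m <- mask
  pad <- function(mm, dr, dc) {
    h <- nrow(mm); w <- ncol(mm)
    out <- matrix(FALSE, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- mm[rs - dr, cs - dc]
    out
  }
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    m <- m & pad(mask, dr, dc)
  }
  m
}

#' Boundary pixels of a binary mask
#'
#' Pixels of `mask` with at least one 8-neighbour outside the mask (frame
#' borders count as outside after padding semantics of erosion).
#'
#' @param mask Logical matrix.
#' @return Logical matrix of the same shape.
#' @export
mask_boundary <- function(mask) mask & !erode8(mask)

#' Minimum pixel distance between two masks
#'
#' Smallest Euclidean distance between any pixel of `a` and any pixel of
#' `b`; 0 when the masks share a pixel. Used to verify the contact contract
#' of generated action videos.
#'
#' @param a,b Logical matrices of equal shape.
#' @return Non-negative scalar; `Inf` if either mask is empty.
#' @export
mask_min_distance <- function(a, b) {
  pa <- which(a, arr.ind = TRUE)
  pb <- which(b, arr.ind = TRUE)
  if (nrow(pa) == 0 || nrow(pb) == 0) return(Inf)
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  sqrt(min(d2))
}
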