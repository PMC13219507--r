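# Shared fixtures, all generated in code.

# Smoothed random texture pair where the content of f2 is f1 rigidly
# shifted by (dx, 0) pixels; returns an interior evaluation mask too.
textured_shift_pair <- function(dx = 3, H = 80, W = 100, seed = 42) {
  set.seed(seed)
  pad <- abs(dx) + 5
  base <- matrix(stats::runif((H + 2 * pad) * (W + 2 * pad), 0, 255),
                 H + 2 * pad, W + 2 * pad)
  for (i in 1:2) {
    acc <- base
    for (dr in -1:1) for (dc in -1:1) {
      acc <- acc + actionclouds:::shift_replicate(base, dr, dc)
    }
    base <- acc / 10
  }
  rows <- (pad + 1):(pad + H)
  f1 <- base[rows, (pad + 1):(pad + W)]
  f2 <- base[rows, (pad + 1 - dx):(pad + W - dx)]
  inner <- matrix(FALSE, H, W)
  inner[15:(H - 14), 15:(W - 14)] <- TRUE
  list(f1 = f1, f2 = f2, inner = inner)
}

# A chiral shape (crescent plus off-axis disk) with all seven Hu moments
# non-zero; scale multiplies every length, ang rotates the whole shape.
chiral_shape <- function(scale = 1, ang = 0, base = 90) {
  H <- 10 * base * scale
  crescent_mask(H, H, H / 2, H / 2, base * scale, 2 * base * scale,
                ang, 2.0) |
    disk_mask(H, H, H / 2 + 5 / 3 * base * scale * cos(ang + 2.6),
              H / 2 + 5 / 3 * base * scale * sin(ang + 2.6),
              base / 2 * scale)
}

# Tiny scene shared by video tests.
tiny_scene <- function(n_frames = 12, seed = 1, ...) {
  scene_config(n_frames = n_frames, seed = seed, ...)
}

object_mask_of <- function(cfg) {
  disk_mask(cfg$frame_height, cfg$frame_width,
            cfg$object_center[1], cfg$object_center[2],
            cfg$shape$object_radius)
}

# Exact confusion matrix object from a 3x3 proportion matrix.
cm_from_prop <- function(prop, n = 900, tm = default_target_map("M1")) {
  dimnames(prop) <- list(action_categories(), target_locations())
  actionclouds:::new_confusion(prop, stats::setNames(rep(n, 3), action_categories()), tm)
}
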