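test_that("optical flow is zero for identical frames and recovers a rigid shift", {
  p <- textured_shift_pair(dx = 0)
  fl0 <- compute_optical_flow(p$f1, p$f1)
  expect_lt(max(abs(c(fl0$u, fl0$v))), 0.1)
  expect_equal(dim(fl0$u), dim(p$f1))

  p3 <- textured_shift_pair(dx = 3)
  fl <- compute_optical_flow(p3$f1, p3$f2)
  expect_lt(abs(stats::median(fl$u[p3$inner]) - 3), 0.5)
  expect_lt(abs(stats::median(fl$v[p3$inner])), 0.5)

  expect_error(compute_optical_flow(p3$f1, p3$f1[1:40, ]), "shape mismatch")
})

test_that("a custom estimator can be plugged in", {
  f <- matrix(0, 20, 20)
  est <- function(a, b) list(u = matrix(2, 20, 20), v = matrix(-1, 20, 20))
  fl <- compute_optical_flow(f, f, estimator = est)
  expect_equal(fl$u[1, 1], 2)
  expect_equal(fl$v[5, 5], -1)
  expect_error(compute_optical_flow(f, f, estimator = "nope"), "unknown flow")
})

test_that("HOF shares the HOG block scheme and bins uniform flow into one bin", {
  zero <- structure(list(u = matrix(0, 64, 64), v = matrix(0, 64, 64)),
                    class = "flow_field")
  hz <- compute_hof(zero)
  expect_true(all(hz[, 3:11] == 0))

  unif <- structure(list(u = matrix(3, 64, 64), v = matrix(0, 64, 64)),
                    class = "flow_field")
  h <- compute_hof(unif)
  # oracle: orientation of (3, 0) is 0 degrees -> first bin of [0, 20)
  expect_true(all(abs(h[, "b1"] - 1) < 1e-9))
  expect_true(all(h[, paste0("b", 2:9)] == 0))

  # same block geometry as HOG on the same raster
  set.seed(5)
  fr <- matrix(runif(64 * 64, 0, 255), 64, 64)
  expect_equal(compute_hog(fr)[, c("cx", "cy")], h[, c("cx", "cy")])
})

test_that("motion energy is the L2 norm of the flow vector", {
  u <- matrix(3, 4, 4); v <- matrix(4, 4, 4)
  fl <- structure(list(u = u, v = v), class = "flow_field")
  me <- compute_motion_energy(fl)
  expect_true(all(me[, "e"] == 5))
  expect_equal(nrow(me), 16)

  set.seed(6)
  fl2 <- structure(list(u = matrix(rnorm(16), 4), v = matrix(rnorm(16), 4)),
                   class = "flow_field")
  m <- matrix(runif(16) < 0.5, 4, 4)
  me2 <- compute_motion_energy(fl2, m)
  expect_equal(sum(me2[, "e"]), sum(sqrt(fl2$u[m]^2 + fl2$v[m]^2)))
})

test_that("silhouette-center kinematics recover speed and direction of a moving disk", {
  H <- 60; W <- 80; n <- 6
  arr <- array(FALSE, c(H, W, n))
  for (t in seq_len(n)) {
    arr[, , t] <- disk_mask(H, W, 20 + 2 * (t - 1), 30, 8)
  }
  kin <- compute_center_kinematics(arr)
  expect_equal(kin$t, 0:(n - 2))
  expect_equal(kin$speed, rep(2, n - 1), tolerance = 1e-9)
  expect_equal(kin$dir_x, rep(1, n - 1), tolerance = 1e-9)
  expect_equal(kin$dir_y, rep(0, n - 1), tolerance = 1e-9)
  # centroid equals the mean of the pixel coordinates by definition
  pix <- which(arr[, , 1], arr.ind = TRUE)
  expect_equal(kin$cx[1], mean(pix[, 2] - 1))

  # static silhouette: zero speed, undefined direction
  still <- array(rep(arr[, , 1], 3), c(H, W, 3))
  ks <- compute_center_kinematics(still)
  expect_true(all(ks$speed == 0))
  expect_true(all(is.na(ks$dir_x)))

  # empty frames are flagged missing
  arr[, , 3] <- FALSE
  km <- compute_center_kinematics(arr)
  expect_true(any(km$missing))
})
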