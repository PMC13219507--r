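test_that("luminance and contrast match their closed forms", {
  expect_equal(compute_luminance(matrix(100, 10, 10)), 100)
  expect_equal(compute_contrast(matrix(100, 10, 10)), 0)

  half <- matrix(c(rep(0, 50), rep(255, 50)), 10, 10)
  expect_equal(compute_luminance(half), 127.5)
  expect_equal(compute_contrast(half), 127.5)   # population SD

  set.seed(1)
  fr <- matrix(runif(100, 0, 255), 10, 10)
  perm <- matrix(sample(fr), 10, 10)
  expect_equal(compute_luminance(fr), compute_luminance(perm))
  expect_equal(compute_contrast(fr), compute_contrast(perm))
})

test_that("HOG geometry: 180x160 full-mask frame yields 399 block histograms", {
  set.seed(2)
  fr <- matrix(runif(180 * 160, 0, 255), 180, 160)
  h <- compute_hog(fr)
  expect_equal(nrow(h), 21 * 19)
  expect_equal(colnames(h), c("cx", "cy", paste0("b", 1:9)))
  expect_true(all(h[, 3:11] >= 0))
  # centers lie inside the frame
  expect_true(all(h[, "cx"] >= 0 & h[, "cx"] < 160))
  expect_true(all(h[, "cy"] >= 0 & h[, "cy"] < 180))
})

test_that("HOG of a uniform frame is all zero; a vertical step loads a single bin", {
  expect_true(all(compute_hog(matrix(7, 64, 64))[, 3:11] == 0))

  step <- matrix(0, 64, 64); step[, 33:64] <- 255
  h <- compute_hog(step)
  # brute-force oracle: Sobel gradient of a vertical step points along +x,
  # unsigned orientation 0 -> first of 9 bins spanning [0, 20) degrees
  nz <- h[rowSums(h[, 3:11]) > 0, , drop = FALSE]
  expect_gt(nrow(nz), 0)
  expect_true(all(abs(nz[, "b1"] - 1) < 1e-9))
  expect_true(all(nz[, paste0("b", 2:9)] == 0))
})

test_that("HOG mask filtering keeps blocks by center pixel and is monotone in the mask", {
  set.seed(3)
  fr <- matrix(runif(96 * 96, 0, 255), 96, 96)
  small <- disk_mask(96, 96, 48, 48, 15)
  big <- disk_mask(96, 96, 48, 48, 30)
  expect_lte(nrow(compute_hog(fr, small)), nrow(compute_hog(fr, big)))
  expect_equal(nrow(compute_hog(fr, matrix(FALSE, 96, 96))), 0)
})

test_that("Canny edges: none on flat or low-contrast frames, perimeter-like count on a rectangle", {
  expect_equal(nrow(compute_edges(matrix(50, 64, 64))), 0)

  # a step of contrast 10 stays below the low threshold after smoothing
  low <- matrix(0, 64, 64); low[, 33:64] <- 10
  expect_equal(nrow(compute_edges(low)), 0)

  fr <- matrix(0, 120, 140); fr[41:70, 51:90] <- 255   # 30 x 40 rectangle
  e <- compute_edges(fr)
  perimeter <- 2 * (30 + 40) - 4
  expect_lt(abs(nrow(e) - perimeter) / perimeter, 0.15)

  # mask restriction: returned pixels are a subset of the mask
  m <- matrix(FALSE, 120, 140); m[, 1:70] <- TRUE
  em <- compute_edges(fr, m)
  expect_true(all(em[, "x"] < 70))
  expect_true(nrow(em) < nrow(e))
})

test_that("silhouette pixels and size agree with counting", {
  m <- matrix(FALSE, 20, 20); m[6:15, 3:12] <- TRUE
  s <- compute_silhouette(m)
  expect_equal(nrow(s), 100)
  expect_equal(compute_silhouette_size(m), 100)
  expect_equal(compute_silhouette_size(matrix(FALSE, 5, 5)), 0)
  expect_equal(nrow(compute_silhouette(matrix(FALSE, 5, 5))), 0)
  # size equals silhouette cardinality for arbitrary masks
  set.seed(4)
  r <- matrix(runif(400) < 0.3, 20, 20)
  expect_equal(compute_silhouette_size(r), nrow(compute_silhouette(r)))
})

test_that("Hu moments: exact translation invariance, scale+rotation within rasterization tolerance", {
  m <- matrix(FALSE, 120, 120)
  m[31:60, 21:70] <- TRUE
  m[20:30, 40:50] <- TRUE
  shifted <- matrix(FALSE, 120, 120)
  shifted[(31:60) + 25, (21:70) + 30] <- TRUE
  shifted[(20:30) + 25, (40:50) + 30] <- TRUE
  expect_equal(compute_hu_moments(m), compute_hu_moments(shifted),
               tolerance = 1e-9)

  h1 <- compute_hu_moments(chiral_shape(1, 0))
  h2 <- compute_hu_moments(chiral_shape(2, pi / 4))
  expect_equal(unname(h2), unname(h1), tolerance = 1e-2)
  rel <- abs(h2 - h1) / abs(h1)
  expect_true(all(rel < 1e-2))

  expect_error(compute_hu_moments(matrix(FALSE, 10, 10)), "empty mask")
})

test_that("mirroring flips only the seventh Hu moment", {
  m <- chiral_shape(1, 0.4, base = 30)
  mirrored <- m[, ncol(m):1]
  hu <- compute_hu_moments(m)
  hum <- compute_hu_moments(mirrored)
  expect_equal(hum[1:6], hu[1:6], tolerance = 1e-12)
  expect_equal(hum[[7]], -hu[[7]], tolerance = 1e-12)
  expect_gt(abs(hu[[7]]), 0)
})
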