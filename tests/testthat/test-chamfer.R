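test_that("chamfer distance matches closed forms and exhaustive enumeration", {
  set.seed(1)
  M <- matrix(rnorm(30), 10)
  expect_equal(chamfer_bruteforce(M, M), 0)

  expect_equal(chamfer_bruteforce(matrix(c(0, 0), 1), matrix(c(3, 4), 1)), 50)

  # M = {(0,0),(1,0)}, N = {(0,1)}: mean(1, 2) + 1 = 2.5
  expect_equal(chamfer_bruteforce(rbind(c(0, 0), c(1, 0)), matrix(c(0, 1), 1)),
               2.5)

  expect_error(chamfer_bruteforce(M, matrix(numeric(0), 0, 3)), "empty cloud")
  expect_error(chamfer_bruteforce(M, matrix(rnorm(8), 2, 4)),
               "dimension mismatch")
  expect_error(chamfer_bruteforce(M, matrix(c(1, NA, 3), 1)), "non-finite")
})

test_that("blocked backend equals the brute-force oracle and ignores block size", {
  set.seed(7)
  for (i in 1:40) {
    D <- sample(2:12, 1)
    A <- matrix(rnorm(sample(1:300, 1) * D, sd = 50), ncol = D)
    B <- matrix(rnorm(sample(1:300, 1) * D, sd = 50), ncol = D)
    bf <- chamfer_bruteforce(A, B)
    expect_equal(chamfer_scalable(A, B, block_size = 64), bf,
                 tolerance = 1e-9)
  }
  A <- matrix(rnorm(600), 200)
  B <- matrix(rnorm(450), 150)
  v1 <- chamfer_scalable(A, B, block_size = 7)
  v2 <- chamfer_scalable(A, B, block_size = 1000)
  expect_equal(v1, v2, tolerance = 1e-12)
  expect_error(chamfer_scalable(A, B, block_size = 0), "block_size")
})

test_that("metric properties: symmetry, point-order invariance, translation and scaling laws", {
  set.seed(8)
  A <- matrix(rnorm(90), 30)
  B <- matrix(rnorm(60), 20)
  cd <- chamfer_scalable(A, B)
  expect_gt(cd, 0)
  expect_equal(chamfer_scalable(B, A), cd)
  expect_equal(chamfer_scalable(A[sample(30), ], B[sample(20), ]), cd)

  shift <- matrix(rep(c(5, -2, 9), each = 1), 1)
  expect_equal(chamfer_scalable(sweep(A, 2, -shift), sweep(B, 2, -shift)), cd,
               tolerance = 1e-9)
  expect_equal(chamfer_scalable(3 * A, 3 * B), 9 * cd, tolerance = 1e-9)
})

test_that("optional per-column z-scoring changes only the scaling of the cloud", {
  set.seed(9)
  A <- cbind(rnorm(40, sd = 100), rnorm(40, sd = 0.01))
  B <- cbind(rnorm(30, sd = 100), rnorm(30, sd = 0.01))
  raw <- chamfer_scalable(A, B)
  z <- chamfer_scalable(A, B, normalize = TRUE)
  expect_false(isTRUE(all.equal(raw, z)))
  # z-scored distance is invariant to per-column rescaling of the input
  z2 <- chamfer_scalable(sweep(A, 2, c(1000, 1e-4), "*"),
                         sweep(B, 2, c(1000, 1e-4), "*"), normalize = TRUE)
  expect_equal(z, z2, tolerance = 1e-9)
})

test_that("distance triplets follow the fixed pair order and detect equal clouds", {
  set.seed(10)
  base <- matrix(rnorm(60), 20)
  same <- list(grasp = base, touch = base, reach = base)
  tr0 <- feature_distance_triplet(same, test_id = 1)
  expect_equal(tr0$pair, c("grasp-touch", "grasp-reach", "touch-reach"))
  expect_equal(tr0$value, c(0, 0, 0))

  distinct <- list(grasp = base + 10, touch = base, reach = base)
  tr <- feature_distance_triplet(distinct, test_id = 2)
  expect_gt(tr$value[1], 0)
  expect_equal(tr$value[1], tr$value[2])
  expect_equal(tr$value[3], 0)

  expect_error(feature_distance_triplet(list(grasp = base, touch = base)),
               "missing category")

  # permuting point order leaves the triplet unchanged
  shuf <- list(grasp = distinct$grasp[sample(20), ], touch = base,
               reach = base[sample(20), ])
  expect_equal(feature_distance_triplet(shuf)$value, tr$value)
})
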