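test_that("cosine similarity obeys identity, orthogonality and scale invariance", {
  a <- c(1, 2, 3, 4)
  expect_equal(cosine_similarity(a, a), 1)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(cosine_similarity(a, 3 * a), 1)
  set.seed(1)
  b <- runif(4)
  expect_equal(cosine_similarity(a, 3 * b), cosine_similarity(a, b))
  expect_error(cosine_similarity(a, c(0, 0, 0, 0)), "zero vector")
  expect_error(cosine_similarity(a, 1:3), "equal")
})

test_that("pooled distance vectors keep the fixed test and pair order", {
  trips <- rbind(
    data.frame(test_id = 2, pair = c("grasp-touch", "grasp-reach", "touch-reach"),
               value = c(4, 5, 6)),
    data.frame(test_id = 1, pair = c("touch-reach", "grasp-touch", "grasp-reach"),
               value = c(3, 1, 2)))
  v <- pool_distance_vector(trips)
  expect_equal(unname(v), 1:6)
  expect_error(pool_distance_vector(trips[-1, ]), "incomplete triplet")
})

test_that("permutation test: determinism, baseline, ties and degenerate inputs", {
  set.seed(2)
  a <- runif(12); b <- runif(12)
  r1 <- permutation_test(a, b, n_perm = 200, seed = 9)
  r2 <- permutation_test(a, b, n_perm = 200, seed = 9)
  expect_identical(r1$null_values, r2$null_values)
  expect_equal(r1$baseline, mean(r1$null_values))
  expect_equal(r1$p_value, sum(r1$null_values > r1$observed) / 200)
  expect_true(r1$observed >= -1 && r1$observed <= 1)

  # all-equal entries: every permutation reproduces the observed value
  const <- rep(2, 12)
  rt <- permutation_test(const, b, n_perm = 50, seed = 1)
  expect_true(all(rt$null_values == rt$observed))
  expect_equal(rt$p_value, 0)   # strict ">" in the tail count

  expect_error(permutation_test(a, b, n_perm = 0), "n_perm")
  expect_error(permutation_test(a, b, unit = "triplet"), NA)
  expect_error(permutation_test(runif(10), runif(10), unit = "triplet"),
               "divisible by 3")
})

test_that("permutation p-values are calibrated under an independent null", {
  set.seed(3)
  n_rep <- 200
  rej <- mean(replicate(n_rep, {
    a <- runif(27); b <- runif(27)
    permutation_test(a, b, n_perm = 400, seed = sample.int(1e6, 1))$p_value < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("matrix-level comparison flattens row-major and pools across tests", {
  set.seed(4)
  cms <- lapply(1:3, function(i) {
    m <- matrix(runif(9), 3); m / rowSums(m)
  })
  same <- compare_matrices(cms, cms, n_perm = 50, seed = 1)
  expect_equal(same$observed, 1)

  trans <- compare_matrices(cms, lapply(cms, t), n_perm = 50, seed = 1)
  expect_lt(trans$observed, 1)

  pooled <- compare_matrices(cms, lapply(cms, t), n_perm = 10, seed = 2)
  manual <- cosine_similarity(unlist(lapply(cms, function(m) as.vector(t(m)))),
                              unlist(lapply(cms, function(m) as.vector(m))))
  expect_equal(pooled$observed, manual)

  per_test <- compare_matrices(cms, lapply(cms, t), pooled = FALSE,
                               n_perm = 10, seed = 2)
  expect_length(per_test, 3)
  expect_error(compare_matrices(cms, cms[1:2]), "length")
})

test_that("correlate_all reports one row per feature/mask and flags collinearity", {
  set.seed(5)
  behavior <- c(runif(9))
  fv <- list("hog|hand" = behavior * 2,         # collinear -> observed 1
             "edges|agent" = runif(9),
             "bad|hand" = rep(0, 9),            # all-zero, skipped
             "short|hand" = runif(6))           # misaligned, skipped
  expect_message(res <- correlate_all(behavior, fv, n_perm = 200, seed = 1),
                 "skipping")
  expect_equal(nrow(res), 2)
  expect_equal(res$feature, c("hog", "edges"))
  expect_equal(res$mask, c("hand", "agent"))
  expect_equal(res$observed[1], 1)
  expect_true(res$significant[1])
})
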