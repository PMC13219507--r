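tm1 <- default_target_map("M1")

test_that("confusion matrices are row-stochastic and exclude invalid trials", {
  tt <- generate_behavior_trials("G-T-R", 400, tm1, seed = 1)
  cm <- build_confusion(tt, tm1)
  expect_equal(unname(rowSums(cm$prop)), rep(1, 3))
  expect_true(all(cm$prop >= 0 & cm$prop <= 1))

  # all-correct trials give the identity-like matrix under the target map
  all_correct <- data.frame(
    presented = rep(action_categories(), each = 5),
    choice = rep(unname(tm1[action_categories()]), each = 5),
    aborted = FALSE)
  cm2 <- build_confusion(all_correct, tm1)
  for (cat in action_categories()) {
    expect_equal(cm2$prop[cat, tm1[[cat]]], 1)
  }

  # a category with only aborted trials errors
  bad <- all_correct
  bad$aborted[bad$presented == "reach"] <- TRUE
  expect_error(build_confusion(bad, tm1), "no valid trials")
})

test_that("uniform random choices at large n give cells near 1/3", {
  tt <- generate_behavior_trials("GTR", 3000, tm1, gtr_mode = "uniform", seed = 2)
  cm <- build_confusion(tt, tm1)
  expect_true(all(abs(cm$prop - 1 / 3) < 0.04))
})

test_that("binomial z-test matches its printed formula and the normal tail", {
  null <- binomial_test(1 / 3, 50)
  expect_equal(null$z, 0)
  expect_equal(null$p_value, 0.5)

  bt <- binomial_test(0.5, 100, chance = 1 / 3)
  z_oracle <- (0.5 - 1 / 3) / sqrt((1 / 3) * (2 / 3) / 100)
  expect_equal(bt$z, z_oracle, tolerance = 1e-6)
  expect_equal(bt$z, 3.535534, tolerance = 1e-6)
  expect_equal(bt$p_value, 1 - pnorm(z_oracle), tolerance = 1e-12)

  # p decreases monotonically in n for a fixed p_hat above chance
  ps <- sapply(c(10, 50, 200, 1000), function(n) binomial_test(0.5, n)$p_value)
  expect_true(all(diff(ps) < 0))

  expect_error(binomial_test(0.5, 100, chance = 1), "chance")
  expect_error(binomial_test(1.5, 10), "p_hat")
})

test_that("performance patterns follow the decision rules", {
  diag9 <- cm_from_prop(rbind(c(0.9, 0.05, 0.05),
                              c(0.05, 0.9, 0.05),
                              c(0.05, 0.05, 0.9)))
  expect_equal(classify_performance_pattern(diag9), "G-T-R")

  gtr_shared <- cm_from_prop(rbind(c(0.9, 0.05, 0.05),
                                   c(0.2, 0.6, 0.2),
                                   c(0.2, 0.6, 0.2)))
  expect_equal(classify_performance_pattern(gtr_shared), "G-TR")

  chance <- cm_from_prop(matrix(1 / 3, 3, 3))
  expect_equal(classify_performance_pattern(chance), "GTR")

  biased <- cm_from_prop(matrix(c(0.1, 0.8, 0.1), 3, 3, byrow = TRUE))
  expect_equal(classify_performance_pattern(biased), "GTR")

  # grasp + touch significant, reach at chance, no shared bias -> other
  partial <- cm_from_prop(rbind(c(0.9, 0.05, 0.05),
                                c(0.05, 0.9, 0.05),
                                c(0.34, 0.33, 0.33)))
  expect_match(classify_performance_pattern(partial), "^other:110$")
})

test_that("classification is invariant to consistent relabeling of targets", {
  tm2 <- default_target_map("M2")
  # same behavior expressed under each subject's map: G-TR with upper bias
  for (tm in list(tm1, tm2)) {
    prop <- matrix(0, 3, 3, dimnames = list(action_categories(), target_locations()))
    prop["grasp", ] <- c(0.9, 0.05, 0.05)
    prop["touch", ] <- c(0.15, 0.7, 0.15)
    prop["reach", ] <- c(0.15, 0.7, 0.15)
    cm <- cm_from_prop(prop, tm = tm)
    expect_equal(classify_performance_pattern(cm), "G-TR")
  }
})

test_that("bias adjustment rewrites only what the pattern dictates", {
  cm <- cm_from_prop(rbind(c(0.9, 0.05, 0.05),
                           c(0.2, 0.6, 0.2),
                           c(0.1, 0.7, 0.2)))
  expect_identical(adjust_confusion(cm, "G-T-R")$prop, cm$prop)

  adj <- adjust_confusion(cm, "G-TR")
  expect_equal(unname(adj$prop["touch", ]), c(0, 0.5, 0.5))
  expect_equal(unname(adj$prop["reach", ]), c(0, 0.5, 0.5))
  expect_equal(adj$prop["grasp", ], cm$prop["grasp", ])

  adj2 <- adjust_confusion(cm, "GTR")
  expect_true(all(abs(adj2$prop - 1 / 3) < 1e-12))

  expect_error(adjust_confusion(cm, "G-R"), "no adjustment")
  # adjusted output stays row-stochastic
  expect_equal(unname(rowSums(adj$prop)), rep(1, 3))
})

test_that("Youden's J: 0 at chance, 1 for perfect discrimination, arithmetic on the definition", {
  chance <- adjust_confusion(cm_from_prop(matrix(1 / 3, 3, 3)), "GTR")
  for (p in action_pairs()) {
    expect_equal(youden_pairwise(chance, p), 0)
  }

  # perfect discrimination: each category puts all mass on its own target
  prop <- matrix(0, 3, 3, dimnames = list(action_categories(), target_locations()))
  for (cat in action_categories()) prop[cat, tm1[[cat]]] <- 1
  perfect <- cm_from_prop(prop)
  for (p in action_pairs()) {
    expect_equal(youden_pairwise(perfect, p), 1)
  }

  # sens 0.8, spec 0.7 -> J = 0.5 (rows already concentrated on the pair's targets)
  prop2 <- matrix(0, 3, 3, dimnames = list(action_categories(), target_locations()))
  prop2["grasp", c("left", "up")] <- c(0.8, 0.2)
  prop2["touch", c("left", "up")] <- c(0.3, 0.7)
  prop2["reach", "right"] <- 1
  expect_equal(youden_pairwise(cm_from_prop(prop2), c("grasp", "touch")), 0.5)

  degenerate <- prop2
  degenerate["touch", ] <- c(0, 0, 1)
  expect_error(youden_pairwise(cm_from_prop(degenerate), c("grasp", "touch")),
               "undefined")
})

test_that("behavior distance triplets mirror the adjusted matrices", {
  chance_cm <- cm_from_prop(matrix(1 / 3, 3, 3))
  tr <- behavior_distance_triplet(chance_cm, "GTR")
  expect_equal(tr$value, c(0, 0, 0))
  expect_equal(tr$pair, c("grasp-touch", "grasp-reach", "touch-reach"))

  gtr_cm <- cm_from_prop(rbind(c(0.9, 0.05, 0.05),
                               c(0.2, 0.6, 0.2),
                               c(0.2, 0.6, 0.2)))
  tr2 <- behavior_distance_triplet(gtr_cm, "G-TR")
  expect_equal(tr2$value[1], tr2$value[2])   # symmetric grasp errors
  expect_gt(tr2$value[1], 0)
  expect_equal(tr2$value[3], 0)
  expect_true(all(tr2$value >= -1 & tr2$value <= 1))
})

test_that("representation patterns map dissociability bits per the >=2-subject rule", {
  sig_tab <- function(gt, gr, tr) {
    data.frame(subject = rep(c("s1", "s2", "s3"), times = 3),
               pair = rep(c("grasp-touch", "grasp-reach", "touch-reach"), each = 3),
               significant = c(gt, gr, tr))
  }
  expect_equal(classify_representation_pattern(
    sig_tab(rep(TRUE, 3), rep(TRUE, 3), rep(TRUE, 3))), "G-T-R")
  expect_equal(classify_representation_pattern(
    sig_tab(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))),
    "G-TR")
  expect_equal(classify_representation_pattern(
    sig_tab(rep(FALSE, 3), rep(FALSE, 3), c(TRUE, TRUE, FALSE))), "T-R")
  expect_equal(classify_representation_pattern(
    sig_tab(rep(FALSE, 3), c(TRUE, TRUE, FALSE), rep(FALSE, 3))), "G-R")
  expect_equal(classify_representation_pattern(
    sig_tab(rep(FALSE, 3), c(TRUE, TRUE, TRUE), c(TRUE, TRUE, FALSE))), "GT-R")
  expect_equal(classify_representation_pattern(
    sig_tab(rep(FALSE, 3), rep(FALSE, 3), rep(FALSE, 3))), "GTR")
  # a combination outside the named taxonomy gets a canonical label
  expect_equal(classify_representation_pattern(
    sig_tab(rep(TRUE, 3), rep(FALSE, 3), rep(FALSE, 3))), "other:100")
  expect_error(classify_representation_pattern(data.frame(a = 1)), "columns")
})

test_that("pattern ratios count labels as percentages summing to 100", {
  labels <- c(rep("G-TR", 10), rep("G-T-R", 6), rep("GTR", 2))
  r <- summarize_pattern_ratios(labels)
  expect_equal(unname(r["G-TR"]), 100 * 10 / 18, tolerance = 1e-12)
  expect_equal(sum(r), 100)
  expect_equal(unname(summarize_pattern_ratios("G-TR")), 100)
  expect_error(summarize_pattern_ratios(character(0)), "at least one")
})
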