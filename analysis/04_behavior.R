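#!/usr/bin/env Rscript
# Stage 4 -- behavioral discriminability.
#
# Each test's trial table becomes a confusion matrix; the session is
# classified into a categorization pattern (G-T-R / G-TR / GTR), the matrix
# is bias-adjusted accordingly, and pairwise Youden's J values form the
# behavior distance triplet. The simulated battery's pattern ratios are
# printed next to the ratios of the 18 reported tests of the two subjects.

suppressPackageStartupMessages(library(actionclouds))

data_root <- "results/data"
tm <- default_target_map("M1")

tests <- sort(list.dirs(data_root, recursive = FALSE))
behavior <- lapply(tests, function(test_dir) {
  test_id <- as.integer(sub("test", "", basename(test_dir)))
  trials <- read_trials(file.path(test_dir, "trials.csv"))
  cm <- build_confusion(trials, tm)
  pattern <- classify_performance_pattern(cm)
  trip <- behavior_distance_triplet(cm, pattern, test_id = test_id)
  cat(sprintf("test %d: pattern %-5s  J = (%.2f, %.2f, %.2f)\n",
              test_id, pattern, trip$value[1], trip$value[2], trip$value[3]))
  list(test_id = test_id, confusion = cm$prop, n_trials = cm$n_trials,
       pattern = pattern,
       triplet = as.list(stats::setNames(trip$value, trip$pair)))
})

jsonlite::write_json(behavior, "results/behavior.json",
                     auto_unbox = TRUE, digits = NA, matrix = "rowmajor")

cat("\nsimulated battery pattern ratios (%):\n")
print(round(summarize_pattern_ratios(sapply(behavior, `[[`, "pattern")), 1))
cat("\nreported 18-test pattern ratios (%):\n")
print(round(summarize_pattern_ratios(generalization_test_patterns()$pattern), 1))
cat("\nwrote results/behavior.json\n")
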