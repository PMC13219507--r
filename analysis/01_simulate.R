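#!/usr/bin/env Rscript
# Stage 1 -- simulate the study's generalization battery.
#
# Nine synthetic generalization tests are generated for one subject (target
# map of M1: grasp/touch/reach -> left/up/right). Each test contributes one
# video per action category with ground-truth body-part masks, plus a
# categorization trial table whose choice statistics follow the pattern
# that subject showed on the corresponding real test (G-T-R on tests 1-3,
# GTR on test 4, G-TR on tests 5-9). Everything is written as plain PNG
# frame sequences and CSV so later stages exercise the package's I/O path.

suppressPackageStartupMessages(library(actionclouds))

out_root <- "results/data"
seed <- 20260925
n_frames <- 24
n_trials <- 300

tm <- default_target_map("M1")
patterns <- subset(generalization_test_patterns(), subject == "M1")$pattern

set.seed(seed)
test_seeds <- sample.int(2^30, 9)
for (i in 1:9) {
  scene <- scene_config(n_frames = n_frames, seed = test_seeds[i])
  battery <- generate_test_battery(1, config = scene, pattern = patterns[i],
                                   n_trials_per_category = n_trials,
                                   target_map = tm, seed = test_seeds[i])
  test <- battery[[1]]
  test_dir <- file.path(out_root, sprintf("test%02d", i))
  for (cat in action_categories()) {
    v <- test$videos[[cat]]
    write_clip(v$clip, file.path(test_dir, cat, "frames"),
               meta = list(category = cat, pattern = patterns[i]))
    write_mask_set(v$masks[c("hand", "agent")],
                   file.path(test_dir, cat, "masks"))
  }
  write_trials(test$trials, file.path(test_dir, "trials.csv"))
  cat(sprintf("test %d (%5s): 3 videos x %d frames, %d trials/category\n",
              i, patterns[i], n_frames, n_trials))
}
cat("simulated battery written to", out_root, "\n")
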