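#!/usr/bin/env Rscript
# Stage 2 -- extract dynamic feature point clouds.
#
# Every video of the simulated battery is reloaded from its PNG frame
# sequence, and per-frame features are pooled along time into point clouds:
# dense features (HOG, edges, flow histograms, motion energy) within the
# hand mask, compact silhouette features (size, Hu moments, kinematics)
# within hand and agent masks, and full-frame luminance/contrast. Clouds
# are cached as RDS for the distance stage.

suppressPackageStartupMessages(library(actionclouds))

data_root <- "results/data"
cloud_root <- "results/clouds"
dir.create(cloud_root, recursive = TRUE, showWarnings = FALSE)

dense_features <- c("hog", "edges", "hof", "motion_energy")
compact_features <- c("silhouette_size", "hu_moments", "kinematics")
lowlevel <- c("luminance", "contrast")

tests <- sort(list.dirs(data_root, recursive = FALSE))
for (test_dir in tests) {
  clouds <- list()
  for (cat in action_categories()) {
    clip <- load_clip(file.path(test_dir, cat, "frames"))
    masks <- load_mask_set(file.path(test_dir, cat, "masks"))
    video <- list(clip = clip, masks = masks)
    cl <- c(extract_clip_features(video, dense_features, "hand"),
            extract_clip_features(video, compact_features, c("hand", "agent")),
            extract_clip_features(video, lowlevel))
    clouds[[cat]] <- cl
    cat(sprintf("%s/%s: %d clouds, %s points total\n",
                basename(test_dir), cat, length(cl),
                format(sum(sapply(cl, function(x) nrow(x$points))), big.mark = ",")))
  }
  saveRDS(clouds, file.path(cloud_root, paste0(basename(test_dir), ".rds")))
}
cat("feature clouds cached under", cloud_root, "\n")
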