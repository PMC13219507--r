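#!/usr/bin/env Rscript
# Stage 5 -- multimodal correlation.
#
# Behavior triplets and each feature's chamfer triplets are pooled across
# tests into distance vectors and compared with cosine similarity; the
# permutation test (10,000 shuffles of the behavioral index values) gives
# a baseline similarity and a p-value per feature/mask cell.

suppressPackageStartupMessages(library(actionclouds))

distances <- utils::read.csv("results/distances.csv")
behavior <- jsonlite::read_json("results/behavior.json", simplifyVector = FALSE)

beh_trips <- do.call(rbind, lapply(behavior, function(b) {
  data.frame(test_id = b$test_id, pair = names(b$triplet),
             value = unlist(b$triplet))
}))
behavior_vector <- pool_distance_vector(beh_trips)

cells <- unique(distances[, c("feature", "mask")])
feature_vectors <- list()
for (i in seq_len(nrow(cells))) {
  sub <- distances[distances$feature == cells$feature[i] &
                   distances$mask == cells$mask[i], ]
  if (nrow(sub) != length(behavior_vector)) next  # incomplete cell
  feature_vectors[[paste0(cells$feature[i], "|", cells$mask[i])]] <-
    pool_distance_vector(sub)
}

results <- correlate_all(behavior_vector, feature_vectors,
                         n_perm = 10000, seed = 20260925)
results <- results[order(results$p_value), ]
utils::write.csv(results, "results/results.csv", row.names = FALSE)

cat("cosine similarity between behavior and feature distance vectors:\n\n")
print(cbind(results[, c("feature", "mask")],
            round(results[, c("observed", "baseline", "p_value")], 4),
            significant = results$significant), row.names = FALSE)
cat(sprintf("\n%d of %d feature|mask cells significant at p < 0.05\n",
            sum(results$significant), nrow(results)))
cat("wrote results/results.csv\n")
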