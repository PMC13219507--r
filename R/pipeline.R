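# End-to-end orchestration: simulate -> extract -> distance -> behavior ->
# correlate, with all thresholds carried in one serializable config.

#' Configuration of a full pipeline run
#'
#' Bundles every knob of the analysis so that a run is fully determined by
#' its config: scene and battery parameters, the feature and mask lists,
#' the chamfer backend, behavioral thresholds and the permutation settings.
#'
#' @param out_dir Output directory for `distances.csv`, `behavior.json`,
#'   `results.csv` and `run_log.json` (`NULL` keeps everything in memory).
#' @param n_tests Number of generalization tests to simulate.
#' @param scene A [scene_config()].
#' @param pattern,n_trials_per_category,accuracy,upper_bias,target_map
#'   Passed to the behavior simulator.
#' @param features,mask_names Feature clouds to extract per video.
#' @param backend Chamfer backend, `"blocked"` or `"bruteforce"`.
#' @param normalize Z-score cloud columns before chamfer.
#' @param alpha,upper_threshold Behavioral classification thresholds.
#' @param n_perm Permutations for the similarity tests.
#' @param seed Master seed.
#' @return List with class `run_config`.
#' @export
pipeline_config <- function(out_dir = NULL,
                            n_tests = 9,
                            scene = scene_config(n_frames = 30),
                            pattern = "G-TR",
                            n_trials_per_category = 300,
                            accuracy = 0.9,
                            upper_bias = 0.8,
                            target_map = default_target_map("M1"),
                            features = c("hog", "edges", "silhouette_size"),
                            mask_names = c("hand", "agent"),
                            backend = "blocked",
                            normalize = FALSE,
                            alpha = 0.05,
                            upper_threshold = 0.5,
                            n_perm = 1000,
                            seed = 1L) {
  structure(list(out_dir = out_dir, n_tests = n_tests, scene = scene,
                 pattern = pattern,
                 n_trials_per_category = n_trials_per_category,
                 accuracy = accuracy, upper_bias = upper_bias,
                 target_map = target_map, features = features,
                 mask_names = mask_names, backend = backend,
                 normalize = normalize, alpha = alpha,
                 upper_threshold = upper_threshold, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulates a battery of generalization tests, extracts the configured
#' feature clouds from every video, computes chamfer-distance triplets per
#' feature/mask cell and Youden's-J behavior triplets per test, pools both
#' sides across tests, and correlates behavior with every feature via the
#' permutation test. Feature/mask cells with an empty cloud in any
#' category are logged and dropped. With `out_dir` set, the stage outputs
#' are written as `distances.csv`, `behavior.json`, `results.csv` and
#' `run_log.json`.
#'
#' @param config A [pipeline_config()].
#' @return List: `battery`, `distances` (data frame), `behavior` (per-test
#'   list), `behavior_vector`, `feature_vectors`, `results` (data frame),
#'   `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  log <- list(seed = config$seed, n_tests = config$n_tests,
              features = config$features, masks = config$mask_names,
              dropped_cells = character(0), counts = list())

  battery <- generate_test_battery(
    config$n_tests, config = config$scene, pattern = config$pattern,
    n_trials_per_category = config$n_trials_per_category,
    target_map = config$target_map, accuracy = config$accuracy,
    upper_bias = config$upper_bias, seed = config$seed)

  # --- feature distances -----------------------------------------------
  distances <- list()
  clouds_per_test <- lapply(battery, function(test) {
    lapply(test$videos, extract_clip_features,
           features = config$features, mask_names = config$mask_names)
  })
  cell_names <- names(clouds_per_test[[1]][[1]])
  for (cell in cell_names) {
    for (i in seq_along(battery)) {
      cl <- lapply(clouds_per_test[[i]], `[[`, cell)
      sizes <- vapply(cl, function(x) nrow(x$points), integer(1))
      log$counts[[paste0("test", i, ":", cell)]] <- unname(sizes)
      if (any(sizes == 0)) {
        log$dropped_cells <- c(log$dropped_cells, paste0("test", i, ":", cell))
        next
      }
      distances[[paste0(cell, ":", i)]] <- feature_distance_triplet(
        cl, backend = config$backend, test_id = i,
        normalize = config$normalize)
    }
  }
  distances <- do.call(rbind, c(distances, list(make.row.names = FALSE)))

  # --- behavior ----------------------------------------------------------
  behavior <- lapply(battery, function(test) {
    cm <- build_confusion(test$trials, config$target_map)
    pattern <- classify_performance_pattern(cm, alpha = config$alpha,
                                            upper_threshold = config$upper_threshold)
    trip <- behavior_distance_triplet(cm, pattern, test_id = test$test_id)
    list(test_id = test$test_id, confusion = cm$prop,
         n_trials = cm$n_trials, pattern = pattern, triplet = trip)
  })
  behavior_trips <- do.call(rbind, lapply(behavior, `[[`, "triplet"))
  behavior_vector <- pool_distance_vector(behavior_trips)

  # --- correlation -------------------------------------------------------
  complete_cells <- Filter(function(cell) {
    sum(distances$feature == sub("\\|.*", "", cell) &
        distances$mask == sub(".*\\|", "", cell)) == 3 * config$n_tests
  }, cell_names)
  feature_vectors <- lapply(complete_cells, function(cell) {
    sub <- distances[distances$feature == sub("\\|.*", "", cell) &
                     distances$mask == sub(".*\\|", "", cell), ]
    pool_distance_vector(sub)
  })
  names(feature_vectors) <- complete_cells
  results <- correlate_all(behavior_vector, feature_vectors,
                           n_perm = config$n_perm, seed = config$seed,
                           alpha = config$alpha)

  bundle <- list(battery = battery, distances = distances,
                 behavior = behavior, behavior_vector = behavior_vector,
                 feature_vectors = feature_vectors, results = results,
                 log = log)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(distances, file.path(config$out_dir, "distances.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(behavior, function(b) list(
        test_id = b$test_id, confusion = b$confusion, n_trials = b$n_trials,
        pattern = b$pattern,
        triplet = as.list(stats::setNames(b$triplet$value, b$triplet$pair)))),
      file.path(config$out_dir, "behavior.json"),
      auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
    utils::write.csv(results, file.path(config$out_dir, "results.csv"),
                     row.names = FALSE)
    log$r_version <- as.character(getRversion())
    jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}
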