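# Pooling per-frame features along the temporal axis into point clouds.

feature_schemas <- list(
  edges           = c("x", "y", "t"),
  silhouette      = c("x", "y", "t"),
  silhouette_size = c("size", "t"),
  hog             = c("cx", "cy", paste0("b", 1:9), "t"),
  hof             = c("cx", "cy", paste0("b", 1:9), "t"),
  hu_moments      = c(paste0("h", 1:7), "t"),
  optical_flow    = c("x", "y", "u", "v", "t"),
  motion_energy   = c("x", "y", "e", "t"),
  kinematics      = c("dx", "dy", "speed", "t"),
  luminance       = c("value", "t"),
  contrast        = c("value", "t")
)

#' Feature point-cloud schemas
#'
#' Column layout of each dynamic feature cloud. Every schema ends with a
#' single time column `t` holding the 0-based frame index (the earlier
#' frame of the pair for flow-derived features).
#'
#' @param feature_name Optional feature name.
#' @return The schema for one feature, or the named list of all schemas.
#' @export
cloud_schema <- function(feature_name = NULL) {
  if (is.null(feature_name)) return(feature_schemas)
  sc <- feature_schemas[[feature_name]]
  if (is.null(sc)) stop("unknown feature: ", feature_name)
  sc
}

#' Pool per-frame feature values into a dynamic feature cloud
#'
#' Stacks the per-frame outputs of one feature, appending the frame index as
#' the time column, into a single N x D point set ready for chamfer
#' comparison. Frames contributing no points (empty mask, no edges) are
#' simply absent from the cloud.
#'
#' @param per_frame List indexed by frame of matrices/vectors holding the
#'   feature's per-frame columns (schema minus `t`). Names are ignored;
#'   list position `i` is frame index `i - 1`.
#' @param feature_name Name from [cloud_schema()].
#' @param mask_name Label of the mask the feature was restricted to.
#' @return List with class `feature_cloud`: `feature`, `mask`, `points`
#'   (N x D matrix with schema column names), `schema`.
#' @export
pool_over_time <- function(per_frame, feature_name, mask_name = "full") {
  schema <- cloud_schema(feature_name)
  d_frame <- length(schema) - 1
  rows <- list()
  for (i in seq_along(per_frame)) {
    m <- per_frame[[i]]
    if (is.null(m) || length(m) == 0) next
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    if (ncol(m) != d_frame) {
      stop(sprintf("frame %d has %d columns; schema of '%s' expects %d",
                   i - 1, ncol(m), feature_name, d_frame))
    }
    if (nrow(m) == 0) next
    rows[[length(rows) + 1]] <- cbind(m, rep(i - 1, nrow(m)))
  }
  points <- if (length(rows) == 0) {
    matrix(numeric(0), 0, length(schema))
  } else {
    do.call(rbind, rows)
  }
  colnames(points) <- schema
  structure(list(feature = feature_name, mask = mask_name,
                 points = points, schema = schema),
            class = "feature_cloud")
}

#' @export
print.feature_cloud <- function(x, ...) {
  cat(sprintf("<feature_cloud %s|%s: %d points x %d dims>\n",
              x$feature, x$mask, nrow(x$points), ncol(x$points)))
  invisible(x)
}

#' Extract one dynamic feature cloud from a clip
#'
#' Runs the per-frame computation of a single feature, restricted to one
#' mask, and pools the results over time. Low-level features (luminance,
#' contrast) use the full frame; silhouette-derived features use the mask
#' itself; gradient and flow features use frame content within the mask.
#' Flow-derived features are indexed by the earlier frame of each pair.
#'
#' @param clip A grayscale [video_clip()] with at least 2 frames for
#'   temporal features.
#' @param mask_array `H x W x n` logical array matching the clip, or `NULL`
#'   for a full-frame mask.
#' @param feature_name Name from [cloud_schema()].
#' @param mask_name Label recorded in the cloud.
#' @param flow_args Extra arguments for [compute_optical_flow()].
#' @param flows Optional precomputed list of flow fields (one per frame
#'   pair, from [precompute_flows()]) shared across flow-derived features.
#' @return A `feature_cloud`.
#' @export
extract_feature_cloud <- function(clip, mask_array, feature_name,
                                  mask_name = "full", flow_args = list(),
                                  flows = NULL) {
  n <- n_frames(clip)
  H <- dim(clip$frames)[1]; W <- dim(clip$frames)[2]
  full <- matrix(TRUE, H, W)
  mask_at <- function(t) {
    if (is.null(mask_array)) full else mask_array[, , t + 1]
  }
  temporal <- feature_name %in% c("optical_flow", "hof", "motion_energy",
                                  "kinematics")
  if (temporal && n < 2) {
    stop("temporal feature '", feature_name, "' needs at least 2 frames")
  }

  if (feature_name == "kinematics") {
    if (is.null(mask_array)) stop("kinematics needs a mask sequence")
    kin <- compute_center_kinematics(mask_array)
    kin <- kin[!kin$missing, , drop = FALSE]
    per_frame <- lapply(seq_len(n - 1) - 1L, function(t) {
      r <- kin[kin$t == t, , drop = FALSE]
      if (nrow(r) == 0) NULL else cbind(r$dx, r$dy, r$speed)
    })
    return(pool_over_time(per_frame, "kinematics", mask_name))
  }

  if (temporal) {
    if (is.null(flows)) flows <- precompute_flows(clip, flow_args)
    if (length(flows) != n - 1) stop("flows must hold one field per frame pair")
    per_frame <- lapply(seq_len(n - 1) - 1L, function(t) {
      fl <- flows[[t + 1]]
      m <- mask_at(t)
      switch(feature_name,
        optical_flow = {
          pix <- which(m, arr.ind = TRUE)
          if (nrow(pix) == 0) NULL
          else cbind(pix[, 2] - 1, pix[, 1] - 1, fl$u[pix], fl$v[pix])
        },
        hof = compute_hof(fl, m),
        motion_energy = compute_motion_energy(fl, m))
    })
    return(pool_over_time(per_frame, feature_name, mask_name))
  }

  per_frame <- lapply(seq_len(n) - 1L, function(t) {
    fr <- get_frame(clip, t)
    m <- mask_at(t)
    switch(feature_name,
      luminance = compute_luminance(fr),
      contrast = compute_contrast(fr),
      hog = compute_hog(fr, m),
      edges = compute_edges(fr, m),
      silhouette = compute_silhouette(m),
      silhouette_size = compute_silhouette_size(m),
      hu_moments = if (any(m)) compute_hu_moments(m) else NULL,
      stop("unknown feature: ", feature_name))
  })
  pool_over_time(per_frame, feature_name, mask_name)
}

#' Extract feature clouds for an action video across masks
#'
#' Convenience wrapper over [extract_feature_cloud()] for a generated
#' `action_video` (clip plus ground-truth mask set). Low-level features are
#' computed once on the full frame regardless of the mask list.
#'
#' @param video An `action_video` from [generate_action_video()], or a list
#'   with elements `clip` and `masks`.
#' @param features Character vector of feature names.
#' @param mask_names Which masks of the set to use for masked features.
#' @param flow_args Passed through to the flow estimator.
#' @return Named list of `feature_cloud`s, names `"<feature>|<mask>"`
#'   (`"<feature>|full"` for luminance/contrast).
#' @export
extract_clip_features <- function(video,
                                  features = c("hog", "edges", "silhouette_size"),
                                  mask_names = c("hand", "agent"),
                                  flow_args = list()) {
  needs_flow <- any(features %in% c("optical_flow", "hof", "motion_energy"))
  flows <- if (needs_flow) precompute_flows(video$clip, flow_args) else NULL
  out <- list()
  for (f in features) {
    if (f %in% c("luminance", "contrast")) {
      out[[paste0(f, "|full")]] <-
        extract_feature_cloud(video$clip, NULL, f, "full", flow_args)
      next
    }
    for (mn in mask_names) {
      arr <- video$masks[[mn]]
      if (is.null(arr)) stop("mask '", mn, "' not present in video")
      out[[paste0(f, "|", mn)]] <-
        extract_feature_cloud(video$clip, arr, f, mn, flow_args, flows = flows)
    }
  }
  out
}

#' Precompute dense flow for every consecutive frame pair of a clip
#'
#' @param clip A grayscale [video_clip()] with at least 2 frames.
#' @param flow_args Extra arguments for [compute_optical_flow()].
#' @return List of `n - 1` flow fields, element `t + 1` for pair `(t, t+1)`.
#' @export
precompute_flows <- function(clip, flow_args = list()) {
  n <- n_frames(clip)
  if (n < 2) stop("temporal features need at least 2 frames")
  lapply(seq_len(n - 1) - 1L, function(t) {
    do.call(compute_optical_flow,
            c(list(get_frame(clip, t), get_frame(clip, t + 1)), flow_args))
  })
}
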