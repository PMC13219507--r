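#' Construct a video clip
#'
#' A clip is an ordered stack of frames plus a frame rate. Frames are stored
#' as an array with the frame index last: `H x W x n` for grayscale or
#' `H x W x 3 x n` for RGB, intensity values in `[0, 255]`.
#'
#' @param frames Numeric array as above.
#' @param fps Frame rate in Hz.
#' @param id Identifier string.
#' @return List with class `video_clip`: `id`, `frames`, `fps`.
#' @export
video_clip <- function(frames, fps = 30, id = "clip") {
  nd <- length(dim(frames))
  if (!nd %in% c(3, 4)) stop("frames must be H x W x n or H x W x 3 x n")
  if (nd == 4 && dim(frames)[3] != 3) stop("color frames must have 3 channels")
  structure(list(id = id, frames = frames, fps = fps), class = "video_clip")
}

#' @export
print.video_clip <- function(x, ...) {
  d <- dim(x$frames)
  n <- d[length(d)]
  cat(sprintf("<video_clip '%s': %d frames of %dx%d px, %g fps>\n",
              x$id, n, d[1], d[2], x$fps))
  invisible(x)
}

n_frames <- function(clip) {
  d <- dim(clip$frames)
  d[length(d)]
}

get_frame <- function(clip, t) {
  # t is the 0-based frame index used throughout the package
  if (length(dim(clip$frames)) == 3) clip$frames[, , t + 1]
  else clip$frames[, , , t + 1]
}

#' Write a clip as a zero-padded PNG frame sequence
#'
#' Frames are written as `frame_0000.png`, `frame_0001.png`, ... plus a
#' `sidecar.json` holding the frame rate and any extra metadata.
#'
#' @param clip A [video_clip()].
#' @param dir Output directory (created if missing).
#' @param meta Named list merged into the sidecar.
#' @return `dir`, invisibly.
#' @export
write_clip <- function(clip, dir, meta = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_frames(clip)
  for (t in seq_len(n) - 1L) {
    fr <- get_frame(clip, t)
    png::writePNG(fr / 255, file.path(dir, sprintf("frame_%04d.png", t)))
  }
  side <- utils::modifyList(list(fps = clip$fps, id = clip$id, n_frames = n),
                            meta)
  jsonlite::write_json(side, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a clip from disk
#'
#' @param path Directory of PNG frames (`kind = "frame_sequence"`) or a
#'   single `.rds` array file (`kind = "array_file"`). Frame files are
#'   ordered lexicographically, so zero-padded indices reproduce temporal
#'   order. The frame rate is read from `sidecar.json` when present,
#'   otherwise from `fps`.
#' @param kind Input layout; video containers (AVI/MP4) are not supported
#'   by this build and raise an error directing to frame sequences.
#' @param fps Fallback frame rate.
#' @return A [video_clip()].
#' @export
load_clip <- function(path, kind = c("frame_sequence", "array_file", "container"),
                      fps = 30) {
  kind <- match.arg(kind)
  if (kind == "container") {
    stop("video containers are not supported; export the clip as a PNG frame sequence")
  }
  if (kind == "array_file") {
    frames <- readRDS(path)
    return(video_clip(frames, fps = fps, id = basename(path)))
  }
  if (!dir.exists(path)) stop("no such directory: ", path)
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG frames found in ", path)
  imgs <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
    # PNG stores k/255 exactly; snap back to the 0..255 integer grid
    round(img * 255, 6)
  })
  shapes <- vapply(imgs, function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(shapes)) > 1) stop("mixed frame shapes in ", path)
  nd <- length(dim(imgs[[1]]))
  frames <- if (is.null(dim(imgs[[1]])) || nd == 2) {
    array(unlist(imgs), dim = c(dim(imgs[[1]]), length(imgs)))
  } else {
    array(unlist(imgs), dim = c(dim(imgs[[1]]), length(imgs)))
  }
  side_path <- file.path(path, "sidecar.json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$fps)) fps <- side$fps
  }
  video_clip(frames, fps = fps, id = basename(path))
}

#' Write and load mask stacks
#'
#' Each named mask of a `mask_set` is written as its own PNG frame sequence
#' under `dir/<name>/`.
#'
#' @param masks Named list of `H x W x n` logical arrays.
#' @param dir Output directory.
#' @return `dir` invisibly, or the reloaded `mask_set`.
#' @export
write_mask_set <- function(masks, dir) {
  for (nm in names(masks)) {
    sub <- file.path(dir, nm)
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    arr <- masks[[nm]]
    for (t in seq_len(dim(arr)[3]) - 1L) {
      png::writePNG(arr[, , t + 1] * 1, file.path(sub, sprintf("frame_%04d.png", t)))
    }
  }
  invisible(dir)
}

#' @rdname write_mask_set
#' @export
load_mask_set <- function(dir) {
  nms <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
  masks <- lapply(nms, function(nm) {
    clip <- load_clip(file.path(dir, nm))
    clip$frames > 127
  })
  names(masks) <- nms
  structure(masks, class = "mask_set")
}

#' Trial table CSV round-trip
#'
#' @param trials A `trial_table` data frame.
#' @param path CSV path with header `presented,choice,aborted`.
#' @return `path` invisibly, or the reloaded `trial_table`.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials)[, c("presented", "choice", "aborted")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tt <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("presented", "choice", "aborted") %in% names(tt)))
  tt$aborted <- as.logical(tt$aborted)
  class(tt) <- c("trial_table", "data.frame")
  tt
}

# --- preprocessing -----------------------------------------------------

# Area-resampling weight matrix mapping n_in samples onto n_out, each output
# cell averaging the input interval it covers (exact box filter).
area_weights <- function(n_in, n_out) {
  if (n_out < 1) stop("target size must be >= 1")
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j0 <- floor(lo) + 1
    j1 <- ceiling(hi)
    for (j in j0:min(j1, n_in)) {
      overlap <- min(hi, j) - max(lo, j - 1)
      if (overlap > 0) W[i, j] <- overlap
    }
    W[i, ] <- W[i, ] / sum(W[i, ])
  }
  W
}

#' Normalize a clip to the analysis raster
#'
#' Converts frames to grayscale with the standard luma weights
#' (0.299 R + 0.587 G + 0.114 B) and resamples them to `height` x `width`
#' with an exact area (box) filter, which anti-aliases and conserves mean
#' intensity. The default raster is 180 x 160 px.
#'
#' @param clip A [video_clip()] (grayscale or RGB).
#' @param height,width Target raster in pixels.
#' @return A grayscale [video_clip()] on the target raster.
#' @export
preprocess <- function(clip, height = 180, width = 160) {
  if (height < 1 || width < 1) stop("target raster must be at least 1x1")
  d <- dim(clip$frames)
  n <- n_frames(clip)
  rgb <- length(d) == 4
  A <- area_weights(d[1], height)
  B <- area_weights(d[2], width)
  out <- array(0, dim = c(height, width, n))
  for (t in seq_len(n) - 1L) {
    fr <- get_frame(clip, t)
    if (rgb) fr <- 0.299 * fr[, , 1] + 0.587 * fr[, , 2] + 0.114 * fr[, , 3]
    out[, , t + 1] <- A %*% fr %*% t(B)
  }
  video_clip(out, fps = clip$fps, id = clip$id)
}
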