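#' Scene configuration for synthetic action videos
#'
#' Parameters of the rendered scene: raster size, frame rate, clip length,
#' positions of the object and of the actor's effector, shape dimensions and
#' the fraction of frames spent approaching the object. Defaults emulate the
#' analysis raster (180 x 160 px at 30 Hz) and a 3 s clip.
#'
#' @param frame_height,frame_width Raster size in pixels.
#' @param fps Frame rate in Hz.
#' @param n_frames Number of frames (>= 2).
#' @param object_center Numeric `(x, y)`, 0-based pixels.
#' @param effector_start Hand-center start position `(x, y)`.
#' @param shape Named list of shape dimensions in pixels: `object_radius`,
#'   `hand_radius`, `arm_width`, `body_center`, `body_rx`, `body_ry`,
#'   `reach_gap` (clearance between hand and object rims in a reach),
#'   `wobble` (amplitude of the seeded perpendicular path jitter).
#' @param approach_fraction Fraction of frames spent moving towards the
#'   object; the remaining frames hold the category-specific end state.
#' @param seed Integer seed for the path jitter.
#' @return List with class `scene_config`.
#' @export
scene_config <- function(frame_height = 180, frame_width = 160, fps = 30,
                         n_frames = 90,
                         object_center = c(x = 110, y = 90),
                         effector_start = c(x = 42, y = 78),
                         shape = list(),
                         approach_fraction = 0.7,
                         seed = 1L) {
  defaults <- list(object_radius = 12, hand_radius = 9, arm_width = 8,
                   body_center = c(x = 16, y = 100), body_rx = 16, body_ry = 30,
                   reach_gap = 6, wobble = 1)
  shape <- utils::modifyList(defaults, shape)
  cfg <- list(frame_height = frame_height, frame_width = frame_width,
              fps = fps, n_frames = as.integer(n_frames),
              object_center = unname(object_center),
              effector_start = unname(effector_start),
              shape = shape,
              approach_fraction = approach_fraction,
              seed = as.integer(seed))
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  if (cfg$n_frames < 2) stop("n_frames must be >= 2")
  if (cfg$approach_fraction <= 0 || cfg$approach_fraction > 1) {
    stop("approach_fraction must be in (0, 1]")
  }
  s <- cfg$shape
  oc <- cfg$object_center
  margin <- s$object_radius + s$hand_radius + 2
  if (oc[1] < margin || oc[1] > cfg$frame_width - 1 - margin ||
      oc[2] < margin || oc[2] > cfg$frame_height - 1 - margin) {
    stop("object (plus hand clearance) does not fit inside the frame")
  }
  d_start <- sqrt(sum((cfg$effector_start - oc)^2))
  d_reach <- s$object_radius + s$hand_radius + s$reach_gap
  if (d_start <= d_reach + 1) {
    stop("effector_start too close to the object to satisfy the contact contract")
  }
  invisible(cfg)
}

# Hand-center trajectory: linear approach from effector_start towards the
# object along the connecting line, with a small seeded perpendicular
# wobble, then the category-specific end distance held for the rest of the
# clip. Returns an n_frames x 2 matrix of (x, y).
hand_trajectory <- function(cfg, end_distance) {
  oc <- cfg$object_center
  st <- cfg$effector_start
  v <- oc - st
  d_start <- sqrt(sum(v^2))
  u <- v / d_start
  perp <- c(-u[2], u[1])
  end <- oc - u * end_distance
  n <- cfg$n_frames
  n_app <- max(1L, min(n - 1L, as.integer(ceiling(cfg$approach_fraction * n))))
  frac <- c(seq(0, 1, length.out = n_app), rep(1, n - n_app))
  # smoothstep easing: velocity ramps up and down like a natural reach
  frac <- frac^2 * (3 - 2 * frac)
  centers <- cbind(st[1] + frac * (end[1] - st[1]),
                   st[2] + frac * (end[2] - st[2]))
  set.seed(cfg$seed)
  wob <- cfg$shape$wobble * sin(seq_len(n) / n * 2 * pi * stats::runif(1, 0.5, 1.5) +
                                stats::runif(1, 0, 2 * pi))
  wob <- wob * frac * (1 - frac) * 4   # zero at both ends of the approach
  centers + outer(wob, perp)
}

#' Generate a synthetic action video with ground-truth masks
#'
#' Renders a grayscale clip of a schematic actor (ellipse body, rectangular
#' arm, disk hand) moving its hand towards a bright disk object, with the
#' contact outcome determined by the action category: a reach stops short of
#' the object (minimum pixel distance stays positive in every frame), a
#' touch ends with the hand claiming pixels on the object's rim but never
#' its interior, and a grasp ends with the hand wrapped as a crescent
#' overlapping the object boundary. Alongside the frames, five nested
#' ground-truth body-part masks are produced per frame: hand, hand-and-arm,
#' agent, agent-without-hand, agent-without-hand-and-arm.
#'
#' @param category One of `"grasp"`, `"touch"`, `"reach"`.
#' @param config A [scene_config()].
#' @return List with elements `clip` (a [video_clip()]) and `masks` (a
#'   `mask_set`: named list of H x W x n_frames logical arrays).
#' @examples
#' v <- generate_action_video("grasp", scene_config(n_frames = 10))
#' dim(v$clip$frames)
#' @export
generate_action_video <- function(category = action_categories(),
                                  config = scene_config()) {
  category <- match.arg(category)
  cfg <- validate_scene_config(config)
  H <- cfg$frame_height; W <- cfg$frame_width
  s <- cfg$shape
  oc <- cfg$object_center
  r_o <- s$object_radius; r_h <- s$hand_radius

  end_distance <- switch(category,
    reach = r_o + r_h + s$reach_gap,
    touch = r_o + r_h,
    grasp = r_o + r_h * 0.55)
  centers <- hand_trajectory(cfg, end_distance)
  n <- cfg$n_frames
  n_app <- max(1L, min(n - 1L, as.integer(ceiling(cfg$approach_fraction * n))))

  object <- disk_mask(H, W, oc[1], oc[2], r_o)
  obj_boundary <- mask_boundary(object)
  body <- ellipse_mask(H, W, s$body_center[1], s$body_center[2],
                       s$body_rx, s$body_ry)
  g <- coord_grids(H, W)
  obj_r2 <- (g$x - oc[1])^2 + (g$y - oc[2])^2

  frames <- array(0, dim = c(H, W, n))
  mk <- function() array(FALSE, dim = c(H, W, n))
  masks <- list(hand = mk(), hand_and_arm = mk(), agent = mk(),
                agent_no_hand = mk(), agent_no_hand_arm = mk())

  approach_dir <- atan2(centers[1, 2] - oc[2], centers[1, 1] - oc[1])

  for (t in seq_len(n)) {
    hc <- centers[t, ]
    in_contact_phase <- t > n_app
    hand <- disk_mask(H, W, hc[1], hc[2], r_h)
    if (in_contact_phase && category == "touch") {
      # claim the facing rim pixels: distance 0 to the object, interior intact
      arc <- obj_boundary &
        (g$x - hc[1])^2 + (g$y - hc[2])^2 <= (r_h + 2)^2
      hand <- hand & obj_r2 > r_o^2   # keep palm off the object entirely
      hand <- hand | arc
    } else if (in_contact_phase && category == "grasp") {
      wrap <- crescent_mask(H, W, oc[1], oc[2], r_o - 2, r_o + 4,
                            approach_dir, 110 * pi / 180)
      hand <- disk_mask(H, W, hc[1], hc[2], r_h * 0.8) | wrap
    } else {
      hand <- hand & obj_r2 > r_o^2   # never clip into the object early
    }
    arm <- segment_mask(H, W, s$body_center[1], s$body_center[2],
                        hc[1], hc[2], s$arm_width)
    agent <- body | arm | hand
    masks$hand[, , t] <- hand
    masks$hand_and_arm[, , t] <- hand | arm
    masks$agent[, , t] <- agent
    masks$agent_no_hand[, , t] <- agent & !hand
    masks$agent_no_hand_arm[, , t] <- agent & !(hand | arm)

    fr <- matrix(20, H, W)
    body_shade <- 120 * (1 - 0.15 * pmin(1,
      ((g$x - s$body_center[1]) / s$body_rx)^2 +
      ((g$y - s$body_center[2]) / s$body_ry)^2))
    fr[body] <- body_shade[body]
    fr[arm] <- 145
    fr[object] <- 235
    hand_shade <- 180 * (1 - 0.15 * pmin(1,
      ((g$x - hc[1])^2 + (g$y - hc[2])^2) / r_h^2))
    fr[hand] <- hand_shade[hand]
    frames[, , t] <- round(fr)   # integer grid: PNG round-trips exactly
  }

  clip <- video_clip(frames, fps = cfg$fps,
                     id = sprintf("%s_seed%d", category, cfg$seed))
  structure(list(clip = clip, masks = structure(masks, class = "mask_set"),
                 category = category, config = cfg),
            class = "action_video")
}

#' Generate a battery of generalization tests
#'
#' A battery is a list of tests; each test holds one synthetic video per
#' action category (sharing a scene layout that varies slightly from test to
#' test) plus one categorization trial table. This mirrors a set of
#' generalization sessions, each built around one novel video per category.
#'
#' @param n_tests Number of tests (>= 1).
#' @param config Base [scene_config()]; per-test layouts jitter the object
#'   and start positions around it.
#' @param pattern Behavioral pattern fed to [generate_behavior_trials()].
#' @param n_trials_per_category Trials per presented category per test.
#' @param target_map A [target_map()].
#' @param accuracy,upper_bias Passed to [generate_behavior_trials()].
#' @param seed Integer master seed; every video and trial table derives its
#'   own sub-seed from it.
#' @return List of `n_tests` lists with elements `videos` (named by
#'   category) and `trials`.
#' @export
generate_test_battery <- function(n_tests, config = scene_config(),
                                  pattern = "G-TR",
                                  n_trials_per_category = 100,
                                  target_map = default_target_map("M1"),
                                  accuracy = 0.9, upper_bias = 0.8,
                                  seed = 1L) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_tests * 4)
  lapply(seq_len(n_tests), function(i) {
    ss <- sub_seeds[(i - 1) * 4 + 1:4]
    set.seed(ss[1])
    cfg_i <- config
    cfg_i$object_center <- config$object_center + round(stats::runif(2, -6, 6))
    cfg_i$effector_start <- config$effector_start + round(stats::runif(2, -5, 5))
    videos <- lapply(seq_along(action_categories()), function(k) {
      cfg_k <- cfg_i
      cfg_k$seed <- ss[2] %% 1000000L + k
      generate_action_video(action_categories()[k], cfg_k)
    })
    names(videos) <- action_categories()
    trials <- generate_behavior_trials(pattern, n_trials_per_category,
                                       target_map, upper_bias = upper_bias,
                                       accuracy = accuracy, seed = ss[3])
    list(test_id = i, videos = videos, trials = trials)
  })
}
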