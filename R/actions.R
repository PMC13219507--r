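#' Action categories and target maps
#'
#' The three manual action categories, in the fixed order used everywhere a
#' pairwise triplet is built: grasp (approach + contact + enclosure), touch
#' (approach + contact), reach (approach only).
#'
#' @return Character vector `c("grasp", "touch", "reach")`.
#' @export
action_categories <- function() c("grasp", "touch", "reach")

#' Category pairs in triplet order
#'
#' Pairwise comparisons in the fixed order (grasp-touch, grasp-reach,
#' touch-reach) used for every distance triplet.
#'
#' @return A list of three length-2 character vectors.
#' @export
action_pairs <- function() {
  list(c("grasp", "touch"), c("grasp", "reach"), c("touch", "reach"))
}

#' Target locations on the choice screen
#' @return Character vector `c("left", "up", "right")`.
#' @export
target_locations <- function() c("left", "up", "right")

#' Construct a category-to-target map
#'
#' A bijective assignment of the three action categories to the three saccade
#' targets. The two built-in maps mirror the two trained subjects: subject
#' "M1" maps grasp/touch/reach to left/up/right; subject "M2" maps
#' grasp/touch/reach to left/right/up.
#'
#' @param grasp,touch,reach Target location for each category.
#' @return Named character vector with class `target_map`.
#' @examples
#' target_map("left", "up", "right")
#' default_target_map("M2")
#' @export
target_map <- function(grasp, touch, reach) {
  tm <- c(grasp = grasp, touch = touch, reach = reach)
  locs <- target_locations()
  if (!all(tm %in% locs) || anyDuplicated(tm) > 0) {
    stop("target_map must be a bijection between categories and {left, up, right}")
  }
  structure(tm, class = "target_map")
}

#' @rdname target_map
#' @param subject `"M1"` or `"M2"`.
#' @export
default_target_map <- function(subject = c("M1", "M2")) {
  subject <- match.arg(subject)
  if (subject == "M1") target_map("left", "up", "right")
  else target_map("left", "right", "up")
}
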