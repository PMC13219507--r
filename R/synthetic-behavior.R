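#' Generate synthetic categorization trials for a behavioral pattern
#'
#' Draws three-alternative forced-choice trials whose category-conditional
#' choice probabilities realize one of the discriminability patterns seen in
#' generalization tests:
#'
#' * `"G-T-R"` — every category is categorized correctly at rate `accuracy`
#'   (errors split evenly over the other two targets): all three actions are
#'   discriminated.
#' * `"G-TR"` — grasp is correct at rate `accuracy`, while touch and reach
#'   both send a fraction `upper_bias` of choices to one shared target
#'   (the upper target by default), so the two are indistinguishable.
#' * `"GTR"` — complete failure: either all categories share the biased
#'   target (`gtr_mode = "bias"`, the default, emulating the strong upper-
#'   target bias seen with novel videos) or all choices are uniform
#'   (`gtr_mode = "uniform"`).
#'
#' A fraction of trials can be marked aborted or answered with no response;
#' such trials carry `choice = "none"` or `aborted = TRUE` and are excluded
#' from confusion matrices downstream.
#'
#' @param pattern `"G-T-R"`, `"G-TR"` or `"GTR"`.
#' @param n_trials_per_category Trials drawn per presented category.
#' @param target_map A [target_map()] giving each category's correct target.
#' @param upper_bias Probability mass on the shared (upper) target for the
#'   non-discriminated categories; in `(1/3, 1]`.
#' @param accuracy Correct-choice probability for discriminated categories;
#'   in `(1/3, 1]`.
#' @param shared_target Target absorbing the bias; defaults to `"up"`.
#' @param gtr_mode `"bias"` or `"uniform"` (GTR pattern only).
#' @param abort_rate,none_rate Probability that a trial is aborted / gets no
#'   response.
#' @param seed Integer seed.
#' @return Data frame with class `trial_table` and columns
#'   `presented`, `choice`, `aborted`.
#' @examples
#' tt <- generate_behavior_trials("G-TR", 100, default_target_map("M1"), seed = 2)
#' table(tt$presented, tt$choice)
#' @export
generate_behavior_trials <- function(pattern = c("G-TR", "G-T-R", "GTR"),
                                     n_trials_per_category,
                                     target_map,
                                     upper_bias = 0.8,
                                     accuracy = 0.9,
                                     shared_target = "up",
                                     gtr_mode = c("bias", "uniform"),
                                     abort_rate = 0,
                                     none_rate = 0,
                                     seed = 1L) {
  pattern <- match.arg(pattern)
  gtr_mode <- match.arg(gtr_mode)
  stopifnot(inherits(target_map, "target_map"))
  if (upper_bias < 0 || upper_bias > 1 || accuracy < 0 || accuracy > 1 ||
      abort_rate < 0 || abort_rate >= 1 || none_rate < 0 || none_rate >= 1) {
    stop("probabilities must lie in [0, 1] (rates in [0, 1))")
  }
  if (!shared_target %in% target_locations()) stop("unknown shared_target")
  locs <- target_locations()

  row_for <- function(p_on, target) {
    p <- rep((1 - p_on) / 2, 3)
    names(p) <- locs
    p[target] <- p_on
    p
  }
  probs <- switch(pattern,
    "G-T-R" = rbind(row_for(accuracy, target_map[["grasp"]]),
                    row_for(accuracy, target_map[["touch"]]),
                    row_for(accuracy, target_map[["reach"]])),
    "G-TR"  = rbind(row_for(accuracy, target_map[["grasp"]]),
                    row_for(upper_bias, shared_target),
                    row_for(upper_bias, shared_target)),
    "GTR"   = if (gtr_mode == "bias") {
                rbind(row_for(upper_bias, shared_target),
                      row_for(upper_bias, shared_target),
                      row_for(upper_bias, shared_target))
              } else {
                matrix(1 / 3, 3, 3, dimnames = list(NULL, locs))
              })
  rownames(probs) <- action_categories()

  set.seed(seed)
  presented <- rep(action_categories(), each = n_trials_per_category)
  choice <- unlist(lapply(action_categories(), function(cat) {
    sample(locs, n_trials_per_category, replace = TRUE, prob = probs[cat, ])
  }))
  aborted <- stats::runif(length(presented)) < abort_rate
  no_resp <- !aborted & stats::runif(length(presented)) < none_rate
  choice[no_resp] <- "none"
  choice[aborted] <- "none"
  tt <- data.frame(presented = presented, choice = choice, aborted = aborted,
                   stringsAsFactors = FALSE, row.names = NULL)
  attr(tt, "target_map") <- target_map
  class(tt) <- c("trial_table", "data.frame")
  tt
}
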