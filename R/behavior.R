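# Behavioral analysis: confusion matrices, binomial generalization tests,
# performance-pattern classification, bias adjustment, Youden's J triplets,
# and decoding-significance pattern summaries.

#' Build a confusion matrix from categorization trials
#'
#' Excludes aborted and no-response trials, then computes for each presented
#' category the proportion of choices towards each target. Rows follow the
#' fixed category order (grasp, touch, reach); columns are the targets
#' (left, up, right).
#'
#' @param trials A `trial_table` (columns `presented, choice, aborted`).
#' @param target_map A [target_map()]; taken from the trial table attribute
#'   when omitted.
#' @return List with class `confusion_matrix`: `prop` (3 x 3 row-stochastic
#'   matrix), `n_trials` (valid trials per row), `target_map`.
#' @export
build_confusion <- function(trials, target_map = NULL) {
  if (is.null(target_map)) target_map <- attr(trials, "target_map")
  stopifnot(inherits(target_map, "target_map"))
  valid <- !trials$aborted & trials$choice %in% target_locations()
  tt <- trials[valid, , drop = FALSE]
  cats <- action_categories(); locs <- target_locations()
  prop <- matrix(0, 3, 3, dimnames = list(cats, locs))
  n_trials <- integer(3); names(n_trials) <- cats
  for (cat in cats) {
    ch <- tt$choice[tt$presented == cat]
    if (length(ch) == 0) stop("no valid trials for category '", cat, "'")
    n_trials[cat] <- length(ch)
    prop[cat, ] <- tabulate(factor(ch, levels = locs), 3) / length(ch)
  }
  new_confusion(prop, n_trials, target_map)
}

new_confusion <- function(prop, n_trials, target_map) {
  stopifnot(all(abs(rowSums(prop) - 1) < 1e-9), all(prop >= 0), all(prop <= 1))
  structure(list(prop = prop, n_trials = n_trials, target_map = target_map),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> choice proportions (rows = presented):\n")
  print(round(x$prop, 3))
  cat("valid trials per row:", paste(x$n_trials, collapse = ", "), "\n")
  invisible(x)
}

correct_rate <- function(cm, category) {
  cm$prop[category, cm$target_map[[category]]]
}

#' One-tailed binomial z-test against chance
#'
#' Tests an observed proportion against chance with the normal
#' approximation \eqn{z = (\hat p - \bar p) / \sqrt{\bar p (1-\bar p)/n}},
#' one-tailed p-value from the standard normal upper tail.
#'
#' @param p_hat Observed proportion of correct trials.
#' @param n Number of trials.
#' @param chance Chance level, strictly inside (0, 1); 1/3 for a
#'   three-alternative task.
#' @return List with class `binomial_result`: `p_hat, n, chance, z,
#'   p_value`.
#' @examples
#' binomial_test(0.5, 100)  # z ~ 3.54, p ~ 2e-4
#' @export
binomial_test <- function(p_hat, n, chance = 1 / 3) {
  if (n < 1) stop("n must be >= 1")
  if (p_hat < 0 || p_hat > 1) stop("p_hat must lie in [0, 1]")
  if (chance <= 0 || chance >= 1) stop("chance must lie strictly in (0, 1)")
  z <- (p_hat - chance) / sqrt(chance * (1 - chance) / n)
  structure(list(p_hat = p_hat, n = n, chance = chance, z = z,
                 p_value = stats::pnorm(z, lower.tail = FALSE)),
            class = "binomial_result")
}

#' Classify a session's performance pattern
#'
#' Applies the decision rules for generalization tests, in order:
#'
#' 1. `G-T-R` — every category's correct rate is significantly above chance
#'    (one-tailed binomial test at `alpha`).
#' 2. `G-TR` — grasping is significant, and touch and reach both send more
#'    than `upper_threshold` of their choices to one shared target that is
#'    not the grasp target (the upper-target bias seen with novel videos).
#' 3. `GTR` — no category is significant, or one shared target dominates
#'    all three rows (clear response bias).
#' 4. Otherwise `other:<gtr significance bits>`.
#'
#' @param cm A `confusion_matrix`.
#' @param alpha Significance level of the per-category binomial tests.
#' @param upper_threshold Shared-target dominance threshold (strict `>`).
#' @return Character pattern label.
#' @export
classify_performance_pattern <- function(cm, alpha = 0.05,
                                         upper_threshold = 0.5) {
  cats <- action_categories()
  sig <- vapply(cats, function(cat) {
    binomial_test(correct_rate(cm, cat), cm$n_trials[[cat]])$p_value < alpha
  }, logical(1))
  if (all(sig)) return("G-T-R")

  locs <- target_locations()
  non_grasp_targets <- setdiff(locs, cm$target_map[["grasp"]])
  shared_tr <- non_grasp_targets[
    cm$prop["touch", non_grasp_targets] > upper_threshold &
    cm$prop["reach", non_grasp_targets] > upper_threshold]
  if (sig[["grasp"]] && length(shared_tr) > 0) return("G-TR")

  dominated <- vapply(locs, function(l) all(cm$prop[, l] > upper_threshold),
                      logical(1))
  if (!any(sig) || any(dominated)) return("GTR")
  paste0("other:", paste(as.integer(sig), collapse = ""))
}

#' Bias-adjust a confusion matrix according to its pattern
#'
#' `G-T-R` sessions are left unchanged. For `G-TR` sessions, where touching
#' and reaching were not discriminated, both rows are set to 50% on each of
#' the upper and right targets (0 on left). For failed `GTR` sessions every
#' cell is set to chance (1/3). Other patterns have no defined adjustment
#' and raise an error.
#'
#' @param cm A `confusion_matrix`.
#' @param pattern Label from [classify_performance_pattern()].
#' @return Adjusted `confusion_matrix`.
#' @export
adjust_confusion <- function(cm, pattern) {
  if (!pattern %in% c("G-T-R", "G-TR", "GTR")) {
    stop("no adjustment defined for pattern '", pattern, "'")
  }
  prop <- cm$prop
  if (pattern == "G-TR") {
    prop["touch", ] <- c(left = 0, up = 0.5, right = 0.5)
    prop["reach", ] <- c(left = 0, up = 0.5, right = 0.5)
  } else if (pattern == "GTR") {
    prop[] <- 1 / 3
  }
  new_confusion(prop, cm$n_trials, cm$target_map)
}

#' Pairwise Youden's J from an adjusted confusion matrix
#'
#' For two categories A and B the 3 x 3 matrix is reduced to a 2 x 2 table:
#' only trials of the two categories and choices of their two corresponding
#' targets are kept, each row renormalized over those two targets.
#' Sensitivity is the renormalized rate of A-target choices on A trials,
#' specificity the rate of B-target choices on B trials, and
#' `J = sensitivity + specificity - 1`.
#'
#' @param cm An adjusted `confusion_matrix`.
#' @param pair Length-2 character vector of distinct categories.
#' @return Scalar J in `[-1, 1]`.
#' @export
youden_pairwise <- function(cm, pair) {
  stopifnot(length(pair) == 2, !anyDuplicated(pair),
            all(pair %in% action_categories()))
  ta <- cm$target_map[[pair[1]]]
  tb <- cm$target_map[[pair[2]]]
  row_a <- cm$prop[pair[1], c(ta, tb)]
  row_b <- cm$prop[pair[2], c(ta, tb)]
  if (sum(row_a) == 0 || sum(row_b) == 0) {
    stop("both relevant target proportions are 0 for a row; J undefined")
  }
  sens <- row_a[[1]] / sum(row_a)
  spec <- row_b[[2]] / sum(row_b)
  sens + spec - 1
}

#' Behavior distance triplet of a session
#'
#' Adjusts the confusion matrix for its pattern, then computes Youden's J
#' for the pairs (grasp-touch, grasp-reach, touch-reach). The triplet is
#' the behavioral counterpart of a feature's chamfer-distance triplet.
#'
#' @param cm A `confusion_matrix`.
#' @param pattern Label from [classify_performance_pattern()]; classified
#'   from `cm` when omitted.
#' @param test_id Identifier carried into the result.
#' @return Data frame with columns `test_id, pair, value`, rows in triplet
#'   order.
#' @export
behavior_distance_triplet <- function(cm, pattern = NULL, test_id = NA) {
  if (is.null(pattern)) pattern <- classify_performance_pattern(cm)
  adj <- adjust_confusion(cm, pattern)
  rows <- lapply(action_pairs(), function(p) {
    data.frame(test_id = test_id, pair = paste(p, collapse = "-"),
               value = youden_pairwise(adj, p))
  })
  out <- do.call(rbind, rows)
  attr(out, "pattern") <- pattern
  out
}

#' Summarize decoding significance into a representation pattern
#'
#' Consumes a table of per-subject significance for the three pairwise
#' decodings and declares a pair dissociable when at least `min_subjects`
#' subjects show significant decoding. The dissociability bits
#' (grasp-touch, grasp-reach, touch-reach) map to: `111` G-T-R, `110` G-TR,
#' `010` G-R, `011` GT-R, `001` T-R, `000` GTR; the remaining combinations
#' are labelled `other:<bits>`.
#'
#' @param sig_table Data frame with columns `subject`, `pair` (values
#'   `"grasp-touch"`, `"grasp-reach"`, `"touch-reach"`) and `significant`
#'   (logical).
#' @param min_subjects Subjects required for dissociability.
#' @return Character pattern label.
#' @export
classify_representation_pattern <- function(sig_table, min_subjects = 2) {
  req <- c("subject", "pair", "significant")
  if (!is.data.frame(sig_table) || !all(req %in% names(sig_table))) {
    stop("sig_table needs columns subject, pair, significant")
  }
  pair_names <- vapply(action_pairs(), paste, character(1), collapse = "-")
  if (!all(sig_table$pair %in% pair_names)) stop("unknown pair label in sig_table")
  if (length(unique(sig_table$subject)) < min_subjects) {
    stop("need at least ", min_subjects, " subjects")
  }
  bits <- vapply(pair_names, function(p) {
    sum(sig_table$significant[sig_table$pair == p]) >= min_subjects
  }, logical(1))
  key <- paste(as.integer(bits), collapse = "")
  switch(key,
         "111" = "G-T-R", "110" = "G-TR", "010" = "G-R",
         "011" = "GT-R", "001" = "T-R", "000" = "GTR",
         paste0("other:", key))
}

#' Pattern label percentages across tests
#'
#' @param labels Character vector of pattern labels (one per test).
#' @return Named numeric vector of percentages summing to 100, in
#'   decreasing order.
#' @examples
#' summarize_pattern_ratios(c(rep("G-TR", 10), rep("G-T-R", 6), rep("GTR", 2)))
#' @export
summarize_pattern_ratios <- function(labels) {
  if (length(labels) == 0) stop("need at least one label")
  tab <- table(labels)
  out <- 100 * as.numeric(tab) / length(labels)
  names(out) <- names(tab)
  sort(out, decreasing = TRUE)
}
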