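#' Per-test categorization patterns of the two trained subjects
#'
#' The pattern assignment of each of the nine generalization tests for both
#' trained subjects: subject M1 showed the fully discriminated G-T-R
#' pattern on tests 1-3, a complete failure (GTR) on test 4 and the
#' grasp-only G-TR pattern on tests 5-9; subject M2 showed G-T-R on tests
#' 1, 2 and 5, GTR on test 3 and G-TR on tests 4 and 6-9. Summarizing these
#' 18 assignments with [summarize_pattern_ratios()] reproduces the reported
#' roughly 56% / 33% / 11% split of G-TR / G-T-R / GTR.
#'
#' @return Data frame with columns `subject`, `test`, `pattern` (18 rows).
#' @export
generalization_test_patterns <- function() {
  data.frame(
    subject = rep(c("M1", "M2"), each = 9),
    test = rep(1:9, 2),
    pattern = c(
      # M1: tests 1-3 G-T-R, test 4 GTR, tests 5-9 G-TR
      "G-T-R", "G-T-R", "G-T-R", "GTR", "G-TR", "G-TR", "G-TR", "G-TR", "G-TR",
      # M2: tests 1, 2, 5 G-T-R, test 3 GTR, tests 4, 6-9 G-TR
      "G-T-R", "G-T-R", "GTR", "G-TR", "G-T-R", "G-TR", "G-TR", "G-TR", "G-TR"),
    stringsAsFactors = FALSE)
}
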