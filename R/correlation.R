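# Relating behavior to stimulus features: pooled distance vectors, cosine
# similarity, permutation null, and matrix-level comparison.

#' Pool per-test distance triplets into one vector
#'
#' Concatenates triplets (grasp-touch, grasp-reach, touch-reach) across
#' tests in increasing `test_id` order, producing the pooled vector that
#' enters the cosine-similarity comparison.
#'
#' @param triplets Data frame with columns `test_id, pair, value` (from
#'   [behavior_distance_triplet()] or [feature_distance_triplet()], rbind-ed
#'   over tests).
#' @return Numeric vector, `3 * n_tests` long, names `<test_id>:<pair>`.
#' @export
pool_distance_vector <- function(triplets) {
  pair_names <- vapply(action_pairs(), paste, character(1), collapse = "-")
  ids <- sort(unique(triplets$test_id))
  vals <- unlist(lapply(ids, function(id) {
    sub <- triplets[triplets$test_id == id, ]
    v <- sub$value[match(pair_names, sub$pair)]
    if (any(is.na(v))) stop("incomplete triplet for test ", id)
    v
  }))
  names(vals) <- as.vector(outer(pair_names, ids,
                                 function(p, i) paste0(i, ":", p)))
  vals
}

#' Cosine similarity of two pooled distance vectors
#'
#' @param a,b Equal-length numeric vectors, each with nonzero norm.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b) || length(a) == 0) {
    stop("vectors must have equal, nonzero length")
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Permutation test of cosine similarity
#'
#' Permutes the entries of `a` (the behavioral index values) `n_perm`
#' times, computing the cosine similarity with `b` for each permutation.
#' The baseline similarity is the mean of this null distribution; the
#' p-value is the proportion of permuted similarities strictly greater
#' than the observed one (so collinear degenerate inputs give p = 0).
#' `unit = "triplet"` permutes whole per-test triplets instead of
#' individual entries.
#'
#' @param a,b Equal-length numeric vectors; `a` is permuted.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param unit `"entry"` (default) or `"triplet"`.
#' @return List with class `permutation_result`: `observed, n_perm,
#'   null_values, baseline, p_value, seed`.
#' @export
permutation_test <- function(a, b, n_perm = 10000, seed = 1L,
                             unit = c("entry", "triplet")) {
  unit <- match.arg(unit)
  if (n_perm < 1) stop("n_perm must be >= 1")
  observed <- cosine_similarity(a, b)
  n <- length(a)
  if (unit == "triplet" && n %% 3 != 0) {
    stop("triplet permutation needs a vector length divisible by 3")
  }
  set.seed(seed)
  null_values <- vapply(seq_len(n_perm), function(i) {
    perm <- if (unit == "entry") {
      a[sample.int(n)]
    } else {
      blocks <- sample.int(n / 3)
      a[as.vector(outer(1:3, (blocks - 1) * 3, "+"))]
    }
    cosine_similarity(perm, b)
  }, numeric(1))
  structure(list(observed = observed, n_perm = n_perm,
                 null_values = null_values,
                 baseline = mean(null_values),
                 p_value = sum(null_values > observed) / n_perm,
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result: observed %.4f, baseline %.4f, p = %.4g (%d perms)>\n",
              x$observed, x$baseline, x$p_value, x$n_perm))
  invisible(x)
}

#' Compare monkey confusion matrices with external prediction matrices
#'
#' Flattens each 3 x 3 matrix in row-major order and applies the same
#' cosine-plus-permutation machinery, either per test or on the pooled
#' concatenation of all tests. Prediction matrices can come from any
#' external classifier (e.g. action-recognition networks).
#'
#' @param monkey_cms List of `confusion_matrix` objects or 3 x 3 matrices.
#' @param predictions List of 3 x 3 matrices, same length and test order.
#' @param pooled If `TRUE` (default) one test over the concatenated
#'   flattenings; otherwise one `permutation_result` per test.
#' @param n_perm,seed Passed to [permutation_test()].
#' @return A `permutation_result`, or a list of them when `pooled = FALSE`.
#' @export
compare_matrices <- function(monkey_cms, predictions, pooled = TRUE,
                             n_perm = 10000, seed = 1L) {
  if (length(monkey_cms) != length(predictions)) {
    stop("monkey and prediction lists differ in length")
  }
  flat <- function(m) {
    if (inherits(m, "confusion_matrix")) m <- m$prop
    if (!all(dim(m) == c(3, 3))) stop("matrices must be 3 x 3")
    as.vector(t(m))   # row-major
  }
  mk <- lapply(monkey_cms, flat)
  pr <- lapply(predictions, flat)
  if (pooled) {
    return(permutation_test(unlist(mk), unlist(pr), n_perm = n_perm,
                            seed = seed))
  }
  lapply(seq_along(mk), function(i) {
    permutation_test(mk[[i]], pr[[i]], n_perm = n_perm, seed = seed + i - 1L)
  })
}

#' Correlate behavior with every feature's distance vector
#'
#' Runs [permutation_test()] between the pooled behavior vector and each
#' feature's pooled vector, returning one row per feature/mask cell with a
#' significance flag at `alpha`. Cells whose vector is missing or all-zero
#' are skipped with a message (e.g. a feature empty in every frame of a
#' mask).
#'
#' @param behavior Pooled behavior vector ([pool_distance_vector()]).
#' @param feature_vectors Named list (`"<feature>|<mask>"`) of pooled
#'   feature vectors of the same length and test order.
#' @param n_perm,seed Passed to [permutation_test()].
#' @param alpha Significance threshold.
#' @return Data frame with columns `feature, mask, observed, baseline,
#'   p_value, significant`.
#' @export
correlate_all <- function(behavior, feature_vectors, n_perm = 10000,
                          seed = 1L, alpha = 0.05) {
  rows <- list()
  for (nm in names(feature_vectors)) {
    fv <- feature_vectors[[nm]]
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    if (is.null(fv) || length(fv) != length(behavior) || all(fv == 0)) {
      message("skipping '", nm, "': missing, misaligned or all-zero vector")
      next
    }
    pr <- permutation_test(behavior, fv, n_perm = n_perm, seed = seed)
    rows[[nm]] <- data.frame(
      feature = parts[1], mask = ifelse(length(parts) > 1, parts[2], "full"),
      observed = pr$observed, baseline = pr$baseline,
      p_value = pr$p_value, significant = pr$p_value < alpha)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
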