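# Chamfer distance between feature point clouds: a reference quadratic
# implementation and a memory-bounded blocked backend.

as_point_matrix <- function(x) {
  if (inherits(x, "feature_cloud")) x <- x$points
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("chamfer distance is undefined for an empty cloud")
  if (any(!is.finite(x))) stop("point cloud contains non-finite values")
  x
}

#' Chamfer distance between two point clouds
#'
#' For each point of `M` the squared Euclidean distance to its nearest
#' neighbour in `N` is averaged over `M`; the same is done from `N` to `M`,
#' and the two means are summed:
#' \deqn{CD(M,N) = \frac{1}{|M|}\sum_{m} \min_n \|m-n\|^2 +
#'       \frac{1}{|N|}\sum_{n} \min_m \|n-m\|^2.}
#' All coordinate columns contribute equally (no per-dimension weighting);
#' `normalize = TRUE` optionally z-scores each column over the pooled
#' points of both clouds before the computation, as a sensitivity analysis
#' for scale ambiguity between columns.
#'
#' `chamfer_bruteforce()` is the straightforward reference; the blocked
#' backend of [chamfer_scalable()] gives identical results while keeping
#' temporary storage bounded by the block size instead of `|M| x |N|`.
#'
#' @param M,N Point matrices (N x D) or `feature_cloud`s over the same
#'   schema.
#' @param normalize Z-score columns over the pooled clouds first.
#' @return Non-negative scalar.
#' @examples
#' chamfer_bruteforce(matrix(c(0, 0), 1), matrix(c(3, 4), 1))  # 50
#' @export
chamfer_bruteforce <- function(M, N, normalize = FALSE) {
  M <- as_point_matrix(M); N <- as_point_matrix(N)
  if (ncol(M) != ncol(N)) stop("dimension mismatch between clouds")
  if (normalize) {
    zs <- normalize_columns(M, N); M <- zs$M; N <- zs$N
  }
  tN <- t(N)
  min_m <- vapply(seq_len(nrow(M)), function(i) {
    min(colSums((tN - M[i, ])^2))
  }, numeric(1))
  tM <- t(M)
  min_n <- vapply(seq_len(nrow(N)), function(j) {
    min(colSums((tM - N[j, ])^2))
  }, numeric(1))
  mean(min_m) + mean(min_n)
}

normalize_columns <- function(M, N) {
  pooled <- rbind(M, N)
  mu <- colMeans(pooled)
  sd <- apply(pooled, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(M = sweep(sweep(M, 2, mu), 2, sd, "/"),
       N = sweep(sweep(N, 2, mu), 2, sd, "/"))
}

# Nearest-neighbour squared distances from each row of A to the rows of B,
# visiting B in blocks so no |A| x |B| matrix is ever materialized. The
# per-dimension difference expansion keeps the arithmetic identical to the
# brute-force path (no a^2 + b^2 - 2ab cancellation).
blocked_min_sqdist <- function(A, B, block_size) {
  nA <- nrow(A); nB <- nrow(B); D <- ncol(A)
  best <- rep(Inf, nA)
  for (a0 in seq(1, nA, by = block_size)) {
    a1 <- min(a0 + block_size - 1, nA)
    Ab <- A[a0:a1, , drop = FALSE]
    best_blk <- rep(Inf, nrow(Ab))
    for (b0 in seq(1, nB, by = block_size)) {
      b1 <- min(b0 + block_size - 1, nB)
      Bb <- B[b0:b1, , drop = FALSE]
      d2 <- matrix(0, nrow(Ab), nrow(Bb))
      for (d in seq_len(D)) {
        d2 <- d2 + outer(Ab[, d], Bb[, d], "-")^2
      }
      best_blk <- pmin(best_blk, apply(d2, 1, min))
    }
    best[a0:a1] <- best_blk
  }
  best
}

#' @rdname chamfer_bruteforce
#' @param block_size Rows per block of the pairwise-distance reduction;
#'   peak temporary memory is `O(block_size^2)`.
#' @export
chamfer_scalable <- function(M, N, block_size = 512, normalize = FALSE) {
  M <- as_point_matrix(M); N <- as_point_matrix(N)
  if (ncol(M) != ncol(N)) stop("dimension mismatch between clouds")
  if (block_size < 1) stop("block_size must be >= 1")
  if (normalize) {
    zs <- normalize_columns(M, N); M <- zs$M; N <- zs$N
  }
  mean(blocked_min_sqdist(M, N, block_size)) +
    mean(blocked_min_sqdist(N, M, block_size))
}

#' Pairwise chamfer distances of one feature between the three categories
#'
#' Given one cloud per action category (same feature, mask and schema),
#' computes the distance triplet in the fixed pair order grasp-touch,
#' grasp-reach, touch-reach.
#'
#' @param clouds_by_category Named list with elements `grasp`, `touch`,
#'   `reach` (matrices or `feature_cloud`s).
#' @param backend `"blocked"` or `"bruteforce"`.
#' @param test_id Identifier carried into the records.
#' @param ... Passed to the backend.
#' @return Data frame with columns `test_id, feature, mask, pair, value`,
#'   three rows in triplet order.
#' @export
feature_distance_triplet <- function(clouds_by_category,
                                     backend = c("blocked", "bruteforce"),
                                     test_id = NA, ...) {
  backend <- match.arg(backend)
  missing <- setdiff(action_categories(), names(clouds_by_category))
  if (length(missing) > 0) {
    stop("missing category cloud(s): ", paste(missing, collapse = ", "))
  }
  first <- clouds_by_category[[1]]
  feature <- if (inherits(first, "feature_cloud")) first$feature else NA
  mask <- if (inherits(first, "feature_cloud")) first$mask else NA
  fun <- if (backend == "blocked") chamfer_scalable else chamfer_bruteforce
  rows <- lapply(action_pairs(), function(p) {
    data.frame(test_id = test_id, feature = feature, mask = mask,
               pair = paste(p, collapse = "-"),
               value = fun(clouds_by_category[[p[1]]],
                           clouds_by_category[[p[2]]], ...))
  })
  do.call(rbind, rows)
}
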