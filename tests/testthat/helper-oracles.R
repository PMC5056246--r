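# Independent oracles used across the suite. These deliberately avoid the
# package's own solution paths: alignment scores by exhaustive enumeration,
# superposition residuals by direct evaluation of candidate rotations.

# Enumerate every strictly monotone matching of an n x m matrix (choose k
# rows and k columns, pair them in sorted order) and return the best total
# weight over matchings whose pairs are all eligible. The empty matching
# scores 0.
enum_monotone_score <- function(S, s_min = 0.2, forbid_self = TRUE) {
  n <- nrow(S); m <- ncol(S)
  eligible <- S >= s_min
  if (forbid_self) {
    k <- seq_len(min(n, m))
    eligible[cbind(k, k)] <- FALSE
  }
  best <- 0
  for (k in seq_len(min(n, m))) {
    rows <- utils::combn(n, k)
    cols <- utils::combn(m, k)
    for (ri in seq_len(ncol(rows))) {
      for (ci in seq_len(ncol(cols))) {
        idx <- cbind(rows[, ri], cols[, ci])
        if (all(eligible[idx])) best <- max(best, sum(S[idx]))
      }
    }
  }
  best
}

# n random proper rotation matrices via normalized quaternions, as an
# n x 9 matrix (row-major per rotation).
random_rotation_bank <- function(n) {
  q <- matrix(rnorm(4 * n), ncol = 4)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
        2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
        2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
}

# Weighted residual of a specific rotation followed by its own optimal
# weighted translation (which aligns the weighted centroids).
candidate_residual <- function(rot9, mobile, target, weights) {
  r <- matrix(rot9, 3, 3, byrow = TRUE)
  w <- weights / sum(weights)
  a <- sweep(mobile, 2, colSums(mobile * w))
  b <- sweep(target, 2, colSums(target * w))
  sum(weights * rowSums((a %*% t(r) - b)^2))
}

# Weighted residual achieved by a transformation.
transform_residual <- function(tr, mobile, target, weights) {
  sum(weights * rowSums((apply_transform(tr, mobile) - target)^2))
}

expect_same_scan <- function(a, b) {
  expect_identical(a$t_scores, b$t_scores)
  expect_identical(a$z_scores, b$z_scores)
  expect_identical(a$best_offset, b$best_offset)
  expect_identical(a$is_symmetric, b$is_symmetric)
  expect_identical(a$axis$direction, b$axis$direction)
  expect_identical(a$axis$point, b$axis$point)
  expect_identical(a$axis$angle_deg, b$axis$angle_deg)
  expect_identical(a$axis$pitch, b$axis$pitch)
}

# angular difference between two unit vectors, sign-blind, in degrees
axis_angle_to <- function(u, v) {
  acos(min(1, abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2)))) * 180 / pi
}
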