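#' Rigid-body transformation
#'
#' A proper rotation `R` plus translation `t`; the action on a point x is
#' `R %*% x + t`. Orthogonality and `det(R) = +1` are validated to 1e-9.
#'
#' @param rotation 3 x 3 proper orthogonal matrix.
#' @param translation length-3 numeric vector (Angstrom).
#' @return An object of class `transformation`.
#' @export
transformation <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!identical(dim(rotation), c(3L, 3L)))
    stop("`rotation` must be 3 x 3", call. = FALSE)
  if (length(translation) != 3L)
    stop("`translation` must have length 3", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("`rotation` is not orthogonal to 1e-9", call. = FALSE)
  if (abs(det(rotation) - 1) > 1e-9)
    stop("`rotation` must be proper (det = +1)", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "transformation")
}

#' Identity transformation
#' @return A [transformation()] with `R = I`, `t = 0`.
#' @export
identity_transform <- function() transformation(diag(3), c(0, 0, 0))

#' @export
print.transformation <- function(x, ...) {
  ang <- rotation_angle_deg(x)
  cat(sprintf("<transformation> rotation %.3f deg, |t| = %.3f A\n",
              ang, sqrt(sum(x$translation^2))))
  invisible(x)
}

as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop("points must be an n x 3 matrix", call. = FALSE)
  storage.mode(points) <- "double"
  points
}

#' Weighted Kabsch superposition
#'
#' Finds the rigid transformation minimizing the weighted sum of squared
#' distances `sum(w_i * ||R m_i + t - x_i||^2)` between mobile points `m`
#' and target points `x`. Solved by SVD of the weighted covariance with the
#' standard determinant-sign correction, so the returned rotation is always
#' proper (no reflection). Collinear inputs are solved but flagged with
#' attribute `degenerate = TRUE` (the rotation about the line is arbitrary).
#'
#' @param mobile n x 3 matrix of points to move.
#' @param target n x 3 matrix of points to match.
#' @param weights nonnegative weights, not all zero (default uniform).
#' @return A [transformation()]; attribute `degenerate` flags rank-deficient
#'   (collinear) inputs.
#' @export
kabsch_superpose <- function(mobile, target, weights = NULL) {
  mobile <- as_points(mobile)
  target <- as_points(target)
  n <- nrow(mobile)
  if (nrow(target) != n)
    stop("`mobile` and `target` must have the same number of points",
         call. = FALSE)
  if (n < 3L)
    stop("need at least 3 point pairs for a superposition", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  weights <- as.numeric(weights)
  if (length(weights) != n)
    stop("`weights` must have one entry per point pair", call. = FALSE)
  if (any(weights < 0) || !all(is.finite(weights)))
    stop("`weights` must be finite and nonnegative", call. = FALSE)
  ws <- sum(weights)
  if (ws <= 0)
    stop("`weights` must not be all zero", call. = FALSE)
  w <- weights / ws

  cm <- colSums(mobile * w)
  ct <- colSums(target * w)
  a <- sweep(mobile, 2, cm)
  b <- sweep(target, 2, ct)
  h <- crossprod(a * w, b)           # sum_i w_i a_i b_i^T
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- transformation(r, ct - as.numeric(r %*% cm))
  # rank < 2 covariance: rotation about the point line is undetermined
  attr(tr, "degenerate") <- sv$d[2] < 1e-8 * max(sv$d[1], .Machine$double.eps)
  tr
}

#' Apply a rigid transformation to points
#'
#' @param transform a [transformation()].
#' @param points n x 3 matrix (or length-3 vector).
#' @return n x 3 matrix of transformed points.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "transformation"))
  points <- as_points(points)
  sweep(points %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' Invert a rigid transformation
#' @param transform a [transformation()].
#' @return The inverse [transformation()].
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "transformation"))
  rt <- t(transform$rotation)
  transformation(rt, -as.numeric(rt %*% transform$translation))
}

#' Compose two rigid transformations
#'
#' Returns the transformation equivalent to applying `first`, then `second`.
#' @param second,first [transformation()] objects.
#' @return A [transformation()].
#' @export
compose_transforms <- function(second, first) {
  stopifnot(inherits(second, "transformation"), inherits(first, "transformation"))
  transformation(second$rotation %*% first$rotation,
                 as.numeric(second$rotation %*% first$translation) +
                   second$translation)
}

#' Weighted root-mean-square deviation
#'
#' `sqrt(sum(w_i ||a_i - b_i||^2) / sum(w_i))`; with uniform weights this is
#' the ordinary RMSD.
#'
#' @param a,b n x 3 coordinate matrices in correspondence.
#' @param weights nonnegative weights with positive sum (default uniform).
#' @return Nonnegative RMSD in the coordinate units.
#' @export
weighted_rmsd <- function(a, b, weights = NULL) {
  a <- as_points(a); b <- as_points(b)
  n <- nrow(a)
  if (n == 0L || nrow(b) != n)
    stop("`a` and `b` must be non-empty and of equal length", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stop("`weights` must be nonnegative with positive sum", call. = FALSE)
  sqrt(sum(weights * rowSums((a - b)^2)) / sum(weights))
}

#' Random rigid transformation
#'
#' A uniformly random proper rotation (QR of a Gaussian matrix with sign
#' fix) plus a uniform translation in `[-max_translation, max_translation]^3`.
#' Used to place synthetic structures in general position.
#'
#' @param seed integer seed.
#' @param max_translation half-width of the translation cube (Angstrom).
#' @return A [transformation()].
#' @export
random_rigid_transform <- function(seed, max_translation = 20) {
  with_seed(seed, {
    qrd <- qr(matrix(rnorm(9), 3, 3))
    q <- qr.Q(qrd)
    q <- q %*% diag(sign(diag(qr.R(qrd))))
    if (det(q) < 0) q[, 3] <- -q[, 3]
    transformation(q, runif(3, -max_translation, max_translation))
  })
}

#' Apply a rigid transformation to a whole structure
#'
#' @param structure a [protein_structure()].
#' @param transform a [transformation()].
#' @return The structure with transformed coordinates.
#' @export
transform_structure <- function(structure, transform) {
  assert_structure(structure)
  structure$xyz <- apply_transform(transform, structure$xyz)
  structure
}
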