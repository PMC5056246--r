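#' Seed correspondence for a circular permutation offset
#'
#' Pairs residue i with residue i + offset for i = 1..N-offset, i.e. the
#' overlap region of the circular shift; wrapped pairs are omitted from the
#' seed (the refinement only needs a starting superposition).
#'
#' @param n_residues total residue count N.
#' @param offset shift k with `1 <= k <= N - 3`.
#' @return An (N - k) x 2 integer matrix of (i, j) index pairs.
#' @export
initial_correspondence <- function(n_residues, offset) {
  n_residues <- as.integer(n_residues)
  offset <- as.integer(offset)
  if (is.na(n_residues) || n_residues < 4L)
    stop("`n_residues` must be >= 4", call. = FALSE)
  if (is.na(offset) || offset < 1L || offset > n_residues - 3L)
    stop("`offset` must lie in 1..N-3", call. = FALSE)
  i <- seq_len(n_residues - offset)
  cbind(i = i, j = i + offset)
}

#' Alignment scan over a set of offsets
#'
#' Runs [rse_refine()] for each requested circular-permutation offset.
#' Offsets are independent of one another, so results do not depend on
#' evaluation order and any subset equals the corresponding slice of the
#' full scan.
#'
#' @param structure a [protein_structure()].
#' @param offsets integer offsets, each in `1..N-3`, non-empty.
#' @param params an [rse_params()].
#' @return List of `alignment_result`, in the order of `offsets`.
#' @export
alignment_scan <- function(structure, offsets, params = rse_params()) {
  assert_structure(structure)
  offsets <- as.integer(offsets)
  if (length(offsets) == 0L)
    stop("`offsets` must be non-empty", call. = FALSE)
  n <- n_residues(structure)
  if (any(is.na(offsets)) || any(offsets < 1L) || any(offsets > n - 3L))
    stop("all offsets must lie in 1..N-3 (N = ", n, ")", call. = FALSE)
  lapply(offsets, function(k) rse_refine(structure, k, params))
}

#' Standardize per-offset T-scores to Z-scores
#'
#' Robust mode (default) standardizes within the protein's own offset-score
#' distribution as `(t - median) / (1.4826 * MAD)`. When the MAD is zero
#' (constant background, possibly with isolated outliers) it falls back to
#' moment standardization `(t - mean) / sd`, and when the standard deviation
#' is also zero all Z-scores are 0. Moment mode uses mean/sd directly.
#'
#' @param t_scores numeric vector of per-offset T-scores (length >= 2).
#' @param z_mode `"robust"` or `"moment"`.
#' @return Numeric Z-scores, same length as `t_scores`.
#' @export
compute_z_scores <- function(t_scores, z_mode = c("robust", "moment")) {
  z_mode <- match.arg(z_mode)
  t_scores <- as.numeric(t_scores)
  if (length(t_scores) < 2L)
    stop("need at least 2 T-scores to standardize", call. = FALSE)
  if (any(!is.finite(t_scores)))
    stop("`t_scores` must be finite", call. = FALSE)
  if (z_mode == "robust") {
    scale <- mad(t_scores)            # 1.4826 * median absolute deviation
    if (scale > 0) return((t_scores - median(t_scores)) / scale)
  }
  s <- sd(t_scores)
  if (s > 0) return((t_scores - mean(t_scores)) / s)
  rep(0, length(t_scores))
}

rotation_angle_deg <- function(transform) {
  ct <- (sum(diag(transform$rotation)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Decompose a rigid transformation into its screw axis
#'
#' The invariant line of a rigid motion: rotation angle from the trace of R
#' (`cos(theta) = (tr(R) - 1) / 2`), axis direction from the rotation's
#' invariant eigenvector with the sign fixed by the antisymmetric part of R
#' (deterministic sign convention near 0 and 180 degrees), pitch as the
#' translation component along the axis, and the on-axis point as the
#' minimum-norm solution of `(I - R) p = t - pitch * u` in the plane
#' perpendicular to the axis. Rotations below 0.5 degrees are flagged
#' `degenerate` (the axis is unreliable) and the point is reported as the
#' origin.
#'
#' @param transform a [transformation()].
#' @return List of class `symmetry_axis`: `direction` (unit 3-vector),
#'   `point` (3-vector, Angstrom), `angle_deg` in `[0, 180]`, `pitch`
#'   (Angstrom per application), `degenerate` flag.
#' @export
extract_symmetry_axis <- function(transform) {
  if (!inherits(transform, "transformation"))
    stop("expected a `transformation`", call. = FALSE)
  r <- transform$rotation
  tv <- transform$translation
  angle <- rotation_angle_deg(transform)

  a <- c(r[3, 2] - r[2, 3], r[1, 3] - r[3, 1], r[2, 1] - r[1, 2]) # 2 sin(theta) u
  if (sqrt(sum(a^2)) > 1e-8) {
    u <- a / sqrt(sum(a^2))
  } else {
    # theta near 0 or 180: columns of R + I span the axis
    b <- r + diag(3)
    k <- which.max(colSums(b^2))
    u <- b[, k] / sqrt(sum(b[, k]^2))
    nz <- which(abs(u) > 1e-8)[1]
    if (!is.na(nz) && u[nz] < 0) u <- -u
  }

  pitch <- sum(tv * u)
  degenerate <- angle < 0.5
  if (degenerate) {
    point <- c(0, 0, 0)
  } else {
    tp <- tv - pitch * u
    point <- as.numeric(MASS::ginv(diag(3) - r) %*% tp)
    point <- point - sum(point * u) * u   # enforce minimum-norm (on-axis) rep
  }
  structure(list(direction = u, point = point, angle_deg = angle,
                 pitch = pitch, degenerate = degenerate),
            class = "symmetry_axis")
}

#' Build the rigid transformation of a screw axis
#'
#' Inverse of [extract_symmetry_axis()]: Rodrigues rotation by `angle_deg`
#' about the unit `direction` through `point`, followed by translation
#' `pitch` along the axis.
#'
#' @param direction axis direction (normalized internally).
#' @param point any point on the axis.
#' @param angle_deg rotation angle in degrees.
#' @param pitch translation along the axis per application (Angstrom).
#' @return A [transformation()].
#' @export
axis_to_transform <- function(direction, point = c(0, 0, 0), angle_deg = 0,
                              pitch = 0) {
  u <- as.numeric(direction)
  nu <- sqrt(sum(u^2))
  if (nu == 0) stop("`direction` must be nonzero", call. = FALSE)
  u <- u / nu
  th <- angle_deg * pi / 180
  k <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  r <- diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
  point <- as.numeric(point)
  transformation(r, pitch * u + as.numeric((diag(3) - r) %*% point))
}

#' @export
print.symmetry_axis <- function(x, ...) {
  cat(sprintf(
    "<symmetry_axis> angle %.2f deg about (%.3f, %.3f, %.3f), pitch %.3f A%s\n",
    x$angle_deg, x$direction[1], x$direction[2], x$direction[3], x$pitch,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# Shared final aggregation used by both the serial and the parallel scan so
# the two paths are arithmetically identical by construction.
finalize_scan <- function(structure, offsets, alignments, cutoff, z_mode) {
  t_scores <- vapply(alignments, function(a) a$t_score, numeric(1))
  z_scores <- compute_z_scores(t_scores, z_mode)
  best_idx <- which.max(z_scores)          # ties -> smallest offset
  angles <- vapply(alignments, function(a) rotation_angle_deg(a$transform),
                   numeric(1))
  best <- alignments[[best_idx]]
  structure(
    list(structure_id = structure$id,
         offsets = as.integer(offsets),
         t_scores = t_scores,
         z_scores = z_scores,
         rotation_angles_deg = angles,
         best_offset = as.integer(offsets[best_idx]),
         best_alignment = best,
         axis = extract_symmetry_axis(best$transform),
         is_symmetric = max(z_scores) >= cutoff,
         cutoff = cutoff,
         z_mode = z_mode),
    class = "scan_result"
  )
}

#' Detect internal symmetry of a protein chain (serial scan)
#'
#' Runs the full alignment scan over offsets `1..N-3`, standardizes the
#' T-scores to Z-scores, picks the best offset (ties broken toward the
#' smallest offset, i.e. the finest repeat), extracts the screw axis from
#' the best alignment's transformation, and calls the structure symmetric
#' when the maximum Z-score reaches `cutoff` (default 8; 10 is the stricter
#' conventional choice).
#'
#' @param structure a [protein_structure()] with at least 5 residues.
#' @param params an [rse_params()].
#' @param cutoff Z-score cutoff for the symmetric verdict.
#' @param z_mode Z standardization mode, see [compute_z_scores()].
#' @return A `scan_result`: per-offset `t_scores`, `z_scores` and rotation
#'   angles, `best_offset`, `best_alignment`, `axis`, `is_symmetric`,
#'   `cutoff`, `z_mode`.
#' @examples
#' s <- make_cn_structure(cn_spec(n_units = 4, unit_size = 6, radius = 10))
#' res <- detect_symmetry(s)
#' res$is_symmetric
#' @export
detect_symmetry <- function(structure, params = rse_params(), cutoff = 8,
                            z_mode = c("robust", "moment")) {
  assert_structure(structure)
  assert_params(params)
  z_mode <- match.arg(z_mode)
  n <- n_residues(structure)
  if (n < 5L)
    stop("need N >= 5 (at least 2 offsets) to standardize scores",
         call. = FALSE)
  offsets <- seq_len(n - 3L)
  alignments <- alignment_scan(structure, offsets, params)
  finalize_scan(structure, offsets, alignments, cutoff, z_mode)
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %s: %d offsets scanned\n", x$structure_id,
              length(x$offsets)))
  cat(sprintf("  best offset %d: T = %.4f, Z = %.3f, angle %.2f deg\n",
              x$best_offset, x$t_scores[match(x$best_offset, x$offsets)],
              max(x$z_scores), x$axis$angle_deg))
  cat(sprintf("  verdict: %s (Z cutoff %g, %s scale)\n",
              if (x$is_symmetric) "SYMMETRIC" else "not symmetric",
              x$cutoff, x$z_mode))
  invisible(x)
}
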