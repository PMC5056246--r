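#' Refinement parameters for the superpose-and-align cycle
#'
#' @param d0 distance scale of the similarity function, Angstrom. A residue
#'   pair at distance `d0` scores 0.5.
#' @param s_min minimum similarity for a pair to enter the alignment
#'   (default 0.2, i.e. pairs further apart than `2 * d0` are dropped).
#' @param max_cycles maximum number of superpose/re-align cycles.
#' @param tol convergence tolerance on the T-score improvement per cycle.
#' @param register_window how far (in residues) the refined alignment of
#'   offset k may deviate from the exact circular-shift register, i.e. only
#'   pairs with `|(j - i) - k| <= register_window` are eligible during
#'   refinement. The default 0 scores each offset as the exact k-shift
#'   hypothesis, which keeps neighbouring offsets in separate basins and
#'   the per-offset score profile sharp; larger values tolerate register
#'   shifts (indels between repeat units) at the cost of score bleed
#'   between nearby offsets, and `Inf` removes the restriction entirely.
#' @param min_shift minimum residue-rank separation `|j - i|` for an
#'   aligned pair. Every chain aligns well to itself shifted by one or two
#'   residues (threading along the backbone), which is self-similarity of
#'   the chain, not internal symmetry; the default 3 excludes these trivial
#'   near-self alignments. Set to 1 to forbid only exact self pairs.
#' @return A list of class `rse_params`.
#' @export
rse_params <- function(d0 = 3.0, s_min = 0.2, max_cycles = 10L, tol = 1e-6,
                       register_window = 0, min_shift = 3L) {
  if (!is.numeric(d0) || d0 <= 0) stop("`d0` must be > 0", call. = FALSE)
  if (!is.numeric(s_min) || s_min < 0 || s_min > 1)
    stop("`s_min` must be in [0, 1]", call. = FALSE)
  max_cycles <- as.integer(max_cycles)
  if (is.na(max_cycles) || max_cycles < 1L)
    stop("`max_cycles` must be a positive integer", call. = FALSE)
  if (!is.numeric(tol) || tol < 0) stop("`tol` must be >= 0", call. = FALSE)
  if (!is.numeric(register_window) || length(register_window) != 1L ||
      is.na(register_window) || register_window < 0)
    stop("`register_window` must be a nonnegative number (Inf allowed)",
         call. = FALSE)
  min_shift <- as.integer(min_shift)
  if (is.na(min_shift) || min_shift < 1L)
    stop("`min_shift` must be a positive integer", call. = FALSE)
  structure(list(d0 = d0, s_min = s_min, max_cycles = max_cycles, tol = tol,
                 register_window = register_window, min_shift = min_shift),
            class = "rse_params")
}

assert_params <- function(params) {
  if (!inherits(params, "rse_params"))
    stop("expected an `rse_params` object (see rse_params())", call. = FALSE)
  invisible(params)
}

#' Distance-derived similarity matrix
#'
#' `S[i, j] = 1 / (1 + (d_ij / d0)^2)` for the Euclidean distances `d_ij`
#' between row i of `coords_a` and row j of `coords_b`. Entries lie in
#' (0, 1] and equal 1 exactly when the points coincide.
#'
#' @param coords_a,coords_b coordinate matrices (n x 3 and m x 3).
#' @param d0 distance scale in Angstrom, > 0.
#' @return An n x m numeric matrix with attribute `d0`.
#' @export
similarity_matrix <- function(coords_a, coords_b, d0 = 3.0) {
  if (!is.numeric(d0) || length(d0) != 1L || d0 <= 0)
    stop("`d0` must be a single positive number", call. = FALSE)
  a <- as_points(coords_a)
  b <- as_points(coords_b)
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("coordinate sets must be non-empty", call. = FALSE)
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0 # guard tiny negative round-off
  s <- 1 / (1 + d2 / d0^2)
  attr(s, "d0") <- d0
  s
}

#' Best strictly monotone non-self alignment of a similarity matrix
#'
#' Maximum-total-weight matching whose pairs are strictly increasing in both
#' indices (dynamic programming, zero gap penalty), restricted to entries
#' with `S[i, j] >= s_min`; with `forbid_self`, diagonal pairs `i == j` are
#' excluded so the trivial self alignment cannot be returned. The traceback
#' is deterministic.
#'
#' @param S numeric similarity matrix (e.g. from [similarity_matrix()]).
#' @param s_min eligibility floor on similarity values.
#' @param forbid_self exclude diagonal pairs.
#' @return List with `pairs` (k x 2 integer matrix of (i, j)), `weights`
#'   (the `S` entries at those pairs) and `score` (their sum).
#' @export
monotone_align <- function(S, s_min = 0.2, forbid_self = TRUE) {
  S <- as.matrix(S)
  if (!is.numeric(S) || any(!is.finite(S)))
    stop("`S` must be a finite numeric matrix", call. = FALSE)
  res <- cpp_monotone_align(S, s_min, isTRUE(forbid_self))
  pairs <- res$pairs
  colnames(pairs) <- c("i", "j")
  weights <- if (nrow(pairs)) S[pairs] else numeric(0)
  list(pairs = pairs, weights = weights, score = res$score)
}

#' Refine one circular-permutation offset by iterated superposition
#'
#' The two-step refinement cycle behind every offset of the alignment scan.
#' The seed correspondence matches residue i to residue i + k; the seed
#' superposition uses uniform weights. Each cycle then (1) re-superposes
#' with the current alignment's similarity values as weights (weighted
#' Kabsch), (2) recomputes the similarity matrix between the original trace
#' and the transformed copy, and (3) re-extracts the best monotone non-self
#' alignment. Iteration stops when the T-score improves by less than `tol`
#' or after `max_cycles`; the best-scoring alignment seen over all cycles is
#' returned together with the transformation that produced it.
#'
#' The alignment is restricted to the seed shift's register neighbourhood
#' (`register_window` in [rse_params()]): without it, refinement at almost
#' every offset of a strongly symmetric structure escapes into the basin of
#' the nearest true symmetry rotation, every offset scores alike, and the
#' per-offset score profile — which the Z-standardization relies on —
#' flattens out.
#'
#' If the alignment collapses below 3 pairs the result is returned as-is
#' with `degenerate = TRUE` and the transformation frozen at the last valid
#' superposition.
#'
#' @param structure a [protein_structure()] with N residues.
#' @param offset circular permutation offset k, `1 <= k <= N - 3`.
#' @param params an [rse_params()].
#' @return List of class `alignment_result`: `pairs`, `pair_weights`,
#'   `t_score`, `transform`, `n_cycles`, `converged`, `degenerate`, `offset`.
#' @export
rse_refine <- function(structure, offset, params = rse_params()) {
  assert_structure(structure)
  assert_params(params)
  n <- n_residues(structure)
  offset <- as.integer(offset)
  if (length(offset) != 1L || is.na(offset) || offset < 1L || offset > n - 3L)
    stop("`offset` must lie in 1..N-3 (N = ", n, ")", call. = FALSE)

  x <- structure$xyz
  # ineligible pairs: register too far from the seed shift, or closer to
  # the diagonal than the non-self margin
  shift <- outer(seq_len(n), seq_len(n), function(i, j) j - i)
  band <- abs(shift) < params$min_shift
  if (is.finite(params$register_window))
    band <- band | abs(shift - offset) > params$register_window
  seed <- initial_correspondence(n, offset)
  tr <- kabsch_superpose(x[seed[, 2], , drop = FALSE],
                         x[seed[, 1], , drop = FALSE],
                         rep(1, nrow(seed)))

  best <- NULL
  prev_t <- -Inf
  converged <- FALSE
  degenerate <- FALSE
  cycle <- 0L
  while (cycle < params$max_cycles) {
    cycle <- cycle + 1L
    y <- apply_transform(tr, x)
    s <- similarity_matrix(x, y, params$d0)
    s[band] <- 0
    al <- monotone_align(s, s_min = params$s_min, forbid_self = TRUE)
    if (is.null(best) || al$score > best$t_score) {
      best <- list(pairs = al$pairs, pair_weights = al$weights,
                   t_score = al$score, transform = tr, n_cycles = cycle)
    }
    if (al$score - prev_t < params$tol) {
      converged <- TRUE
      break
    }
    prev_t <- al$score
    if (nrow(al$pairs) < 3L) {
      degenerate <- TRUE
      break
    }
    tr <- kabsch_superpose(x[al$pairs[, 2], , drop = FALSE],
                           x[al$pairs[, 1], , drop = FALSE],
                           al$weights)
  }

  structure(
    c(best, list(converged = converged, degenerate = degenerate,
                 offset = offset)),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> offset %d: T = %.4f over %d pairs, %d cycle(s)%s%s\n",
    x$offset, x$t_score, nrow(x$pairs), x$n_cycles,
    if (x$converged) ", converged" else "",
    if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}
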