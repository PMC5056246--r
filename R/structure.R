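#' Construct a CA-trace protein structure
#'
#' The internal representation of one protein chain: an ordered CA trace.
#' All scan operations index residues by their 1-based rank in this trace,
#' not by author numbering; `resno` and `ins` are carried as labels only.
#'
#' @param xyz numeric N x 3 matrix of CA coordinates in Angstrom.
#' @param id character label for the structure.
#' @param resno integer residue numbers (labels; default `1:N`).
#' @param aa one-letter amino-acid codes (`"X"` for unknown; default all X).
#' @param ins insertion-code labels (default empty strings).
#' @return An object of class `protein_structure` with fields `id`, `resno`,
#'   `ins`, `aa` and `xyz`.
#' @examples
#' s <- protein_structure(matrix(rnorm(30), ncol = 3), id = "toy")
#' n_residues(s)
#' @export
protein_structure <- function(xyz, id = "structure", resno = NULL,
                              aa = NULL, ins = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L)
    stop("`xyz` must be an N x 3 coordinate matrix", call. = FALSE)
  n <- nrow(xyz)
  if (n < 4L)
    stop("structure too short: need at least 4 CA positions, got ", n,
         call. = FALSE)
  if (!all(is.finite(xyz)))
    stop("coordinates must be finite", call. = FALSE)
  storage.mode(xyz) <- "double"
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  if (is.null(resno)) resno <- seq_len(n)
  if (is.null(aa)) aa <- rep("X", n)
  if (is.null(ins)) ins <- rep("", n)
  if (length(resno) != n || length(aa) != n || length(ins) != n)
    stop("`resno`, `aa` and `ins` must each have one entry per residue",
         call. = FALSE)
  structure(
    list(id = as.character(id)[1], resno = as.integer(resno),
         ins = as.character(ins), aa = as.character(aa), xyz = xyz),
    class = "protein_structure"
  )
}

#' Number of residues in a structure
#'
#' @param structure a [protein_structure()].
#' @return Integer residue count (the scan's N).
#' @export
n_residues <- function(structure) {
  stopifnot(inherits(structure, "protein_structure"))
  nrow(structure$xyz)
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure> %s: %d CA residues\n", x$id, n_residues(x)))
  invisible(x)
}

assert_structure <- function(structure) {
  if (!inherits(structure, "protein_structure"))
    stop("expected a `protein_structure` object", call. = FALSE)
  invisible(structure)
}
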