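#' Read a protein chain from a PDB file as a CA trace
#'
#' Parses standard PDB ATOM records (via bio3d) and keeps one CA coordinate
#' per residue of the selected chain: HETATM records are ignored, residues
#' lacking a CA atom are dropped (with a message), and for alternate
#' locations the first-listed conformer is kept. Internal residue indexing
#' is the 1-based rank in the filtered CA list; author numbering and
#' insertion codes are carried as labels. Chain breaks (consecutive CA-CA
#' distance > 4.5 Angstrom) are noted in a message.
#'
#' @param path PDB file path.
#' @param chain chain identifier; default: first chain in file order.
#' @param model model index for multi-model files (default 1).
#' @return A [protein_structure()].
#' @export
read_structure <- function(path, chain = NULL, model = 1L) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("could not read PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM" & atoms$elety == "CA", , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop("no CA ATOM records found in '", path, "'", call. = FALSE)

  chains <- unique(atoms$chain)
  if (is.null(chain)) {
    chain <- chains[1]
  } else if (!chain %in% chains) {
    stop("chain '", chain, "' not found; available: ",
         paste(chains, collapse = ", "), call. = FALSE)
  }
  atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]

  # altloc / duplicate CA records: keep the first-listed conformer
  ins <- atoms$insert
  ins[is.na(ins)] <- ""
  key <- paste(atoms$resno, ins, sep = "|")
  keep <- !duplicated(key)
  atoms <- atoms[keep, , drop = FALSE]
  ins <- ins[keep]

  model <- as.integer(model)
  if (model == 1L) {
    xyz <- cbind(atoms$x, atoms$y, atoms$z)
  } else {
    if (is.na(model) || model < 1L || model > nrow(pdb$xyz))
      stop("model ", model, " not present (file has ", nrow(pdb$xyz),
           " model(s))", call. = FALSE)
    idx <- bio3d::atom2xyz(as.integer(rownames(atoms)))
    xyz <- matrix(pdb$xyz[model, idx], ncol = 3, byrow = TRUE)
  }

  miss <- !stats::complete.cases(xyz)
  if (any(miss)) {
    message("dropping ", sum(miss), " residue(s) without usable CA coordinates")
    atoms <- atoms[!miss, , drop = FALSE]
    ins <- ins[!miss]
    xyz <- xyz[!miss, , drop = FALSE]
  }
  if (nrow(xyz) < 4L)
    stop("chain too short: only ", nrow(xyz),
         " CA atoms after filtering (need >= 4)", call. = FALSE)

  aa <- suppressWarnings(bio3d::aa321(atoms$resid))
  aa[is.na(aa) | !nzchar(aa)] <- "X"

  gaps <- which(sqrt(rowSums(diff(xyz)^2)) > 4.5)
  if (length(gaps))
    message("chain break(s) after CA rank: ", paste(gaps, collapse = ", "))

  protein_structure(xyz,
                    id = sub("\\.(pdb|ent)$", "", basename(path)),
                    resno = atoms$resno, aa = aa, ins = ins)
}

assert_scan_result <- function(result) {
  if (!inherits(result, "scan_result"))
    stop("expected a `scan_result` object", call. = FALSE)
  need <- c("structure_id", "offsets", "t_scores", "z_scores",
            "rotation_angles_deg", "best_offset", "axis", "is_symmetric",
            "cutoff")
  missing <- setdiff(need, names(result))
  if (length(missing) || length(result$offsets) == 0L ||
      length(result$t_scores) != length(result$offsets) ||
      length(result$z_scores) != length(result$offsets))
    stop("incomplete scan result", call. = FALSE)
  invisible(result)
}

#' Write a scan report
#'
#' TSV: one data row per scanned offset with columns `offset`, `t_score`,
#' `z_score`, `rotation_angle_deg`. JSON: the full scan result including the
#' symmetry axis, verdict and best alignment, at full numeric precision
#' (round-trips through [read_scan_report()] to 1e-9 relative precision).
#'
#' @param result a `scan_result` from [detect_symmetry()] or [run_parallel()].
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_scan_report <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  assert_scan_result(result)
  if (format == "tsv") {
    df <- data.frame(offset = result$offsets,
                     t_score = result$t_scores,
                     z_score = result$z_scores,
                     rotation_angle_deg = result$rotation_angles_deg)
    write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                file = path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    ba <- result$best_alignment
    payload <- list(
      structure_id = result$structure_id,
      offsets = result$offsets,
      t_scores = result$t_scores,
      z_scores = result$z_scores,
      rotation_angles_deg = result$rotation_angles_deg,
      best_offset = result$best_offset,
      is_symmetric = result$is_symmetric,
      cutoff = result$cutoff,
      z_mode = result$z_mode,
      axis = list(direction = result$axis$direction,
                  point = result$axis$point,
                  angle_deg = result$axis$angle_deg,
                  pitch = result$axis$pitch,
                  degenerate = result$axis$degenerate),
      best_alignment = list(offset = ba$offset,
                            pairs = unname(ba$pairs),
                            pair_weights = ba$pair_weights,
                            t_score = ba$t_score,
                            n_cycles = ba$n_cycles,
                            converged = ba$converged,
                            degenerate = ba$degenerate,
                            rotation = unname(ba$transform$rotation),
                            translation = ba$transform$translation)
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read back a JSON scan report
#'
#' @param path a JSON file written by [write_scan_report()].
#' @return A `scan_result`.
#' @export
read_scan_report <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  tr <- transformation(x$best_alignment$rotation,
                       x$best_alignment$translation)
  pairs <- x$best_alignment$pairs
  if (is.null(pairs) || length(pairs) == 0L) {
    pairs <- matrix(integer(0), 0, 2)
  } else if (is.null(dim(pairs))) {
    pairs <- matrix(as.integer(pairs), ncol = 2)
  }
  colnames(pairs) <- c("i", "j")
  ba <- structure(list(pairs = pairs,
                       pair_weights = as.numeric(x$best_alignment$pair_weights),
                       t_score = x$best_alignment$t_score,
                       transform = tr,
                       n_cycles = as.integer(x$best_alignment$n_cycles),
                       converged = x$best_alignment$converged,
                       degenerate = x$best_alignment$degenerate,
                       offset = as.integer(x$best_alignment$offset)),
                  class = "alignment_result")
  axis <- structure(list(direction = as.numeric(x$axis$direction),
                         point = as.numeric(x$axis$point),
                         angle_deg = x$axis$angle_deg,
                         pitch = x$axis$pitch,
                         degenerate = x$axis$degenerate),
                    class = "symmetry_axis")
  structure(list(structure_id = x$structure_id,
                 offsets = as.integer(x$offsets),
                 t_scores = as.numeric(x$t_scores),
                 z_scores = as.numeric(x$z_scores),
                 rotation_angles_deg = as.numeric(x$rotation_angles_deg),
                 best_offset = as.integer(x$best_offset),
                 best_alignment = ba,
                 axis = axis,
                 is_symmetric = x$is_symmetric,
                 cutoff = x$cutoff,
                 z_mode = x$z_mode),
            class = "scan_result")
}
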