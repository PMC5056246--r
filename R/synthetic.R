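#' Specification of a Cn-symmetric toy structure
#'
#' Parameters of a cyclic (Cn) CA-trace generator: one random-walk motif of
#' `unit_size` residues is replicated `n_units` times around the z axis.
#'
#' @param n_units cyclic order n, >= 2.
#' @param unit_size residues per repeat unit, >= 3.
#' @param radius distance of the unit centroid from the symmetry axis
#'   (Angstrom).
#' @param noise_sd isotropic Gaussian coordinate noise, Angstrom, >= 0.
#' @param seed integer seed for the motif walk and the noise.
#' @param rise translation along the axis per unit (Angstrom); 0 gives a
#'   pure rotation (Cn), nonzero gives a helical/screw arrangement.
#' @return A list of class `cn_spec`.
#' @export
cn_spec <- function(n_units, unit_size, radius = 10, noise_sd = 0,
                    seed = 1L, rise = 0) {
  n_units <- as.integer(n_units)
  unit_size <- as.integer(unit_size)
  if (is.na(n_units) || n_units < 2L)
    stop("`n_units` must be an integer >= 2", call. = FALSE)
  if (is.na(unit_size) || unit_size < 3L)
    stop("`unit_size` must be an integer >= 3", call. = FALSE)
  if (!is.numeric(radius) || radius < 0)
    stop("`radius` must be >= 0", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!is.numeric(rise))
    stop("`rise` must be numeric", call. = FALSE)
  structure(list(n_units = n_units, unit_size = unit_size, radius = radius,
                 noise_sd = noise_sd, seed = as.integer(seed), rise = rise),
            class = "cn_spec")
}

# Random CA walk: `n` positions with successive distances of exactly `step`.
random_walk_chain <- function(n, step = 3.8) {
  dirs <- matrix(rnorm(3 * (n - 1)), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rbind(c(0, 0, 0), apply(dirs * step, 2, cumsum))
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

#' Generate a Cn-symmetric CA trace (positive control)
#'
#' Builds one random-walk motif (successive CA-CA distance 3.8 Angstrom),
#' moves its centroid to distance `radius` from the z axis, and appends
#' `n_units` copies each rotated by `360 / n_units` degrees about z (plus
#' `rise` along z per unit, if requested), then adds isotropic Gaussian
#' noise. With `noise_sd = 0` and `rise = 0`, rotating the whole structure
#' by `360 / n_units` degrees about z and shifting residue rank by
#' `unit_size` maps every CA exactly onto another CA — the ground truth the
#' symmetry scan should recover. Deterministic for a fixed seed.
#'
#' @param spec a [cn_spec()].
#' @return A [protein_structure()] with `n_units * unit_size` residues.
#' @examples
#' s <- make_cn_structure(cn_spec(n_units = 7, unit_size = 10, radius = 12))
#' n_residues(s)
#' @export
make_cn_structure <- function(spec) {
  if (!inherits(spec, "cn_spec"))
    stop("`spec` must be a `cn_spec` object", call. = FALSE)
  with_seed(spec$seed, {
    motif <- random_walk_chain(spec$unit_size)
    motif <- sweep(motif, 2, colMeans(motif))           # centroid at origin
    motif <- sweep(motif, 2, c(spec$radius, 0, 0), `+`) # offset from axis
    step_deg <- 360 / spec$n_units
    xyz <- do.call(rbind, lapply(seq_len(spec$n_units) - 1L, function(u) {
      sweep(motif %*% t(rot_z(u * step_deg)), 2,
            c(0, 0, u * spec$rise), `+`)
    }))
    if (spec$noise_sd > 0)
      xyz <- xyz + matrix(rnorm(length(xyz), sd = spec$noise_sd),
                          ncol = 3)
    protein_structure(
      xyz,
      id = sprintf("C%d_u%d_seed%d", spec$n_units, spec$unit_size, spec$seed),
      aa = rep("A", nrow(xyz))
    )
  })
}

#' Generate a random-coil CA trace (negative control)
#'
#' Self-avoiding-ish random walk: successive CA-CA distance 3.8 Angstrom,
#' with every non-consecutive pair kept at least 3.0 Angstrom apart by
#' rejection sampling. Deterministic per seed.
#'
#' @param n_residues number of residues, >= 4.
#' @param seed integer seed.
#' @return A [protein_structure()].
#' @export
make_random_coil <- function(n_residues, seed = 1L) {
  n_residues <- as.integer(n_residues)
  if (is.na(n_residues) || n_residues < 4L)
    stop("`n_residues` must be an integer >= 4", call. = FALSE)
  step <- 3.8
  min_sep <- 3.0
  with_seed(seed, {
    for (restart in 1:100) {
      xyz <- matrix(NA_real_, n_residues, 3)
      xyz[1, ] <- c(0, 0, 0)
      ok <- TRUE
      for (i in 2:n_residues) {
        placed <- FALSE
        for (try in 1:1000) {
          d <- rnorm(3)
          cand <- xyz[i - 1, ] + step * d / sqrt(sum(d^2))
          if (i > 2) {
            prev <- xyz[seq_len(i - 2), , drop = FALSE]
            if (min(rowSums(sweep(prev, 2, cand)^2)) < min_sep^2) next
          }
          xyz[i, ] <- cand
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok)
        return(protein_structure(xyz,
                                 id = sprintf("coil%d_seed%d", n_residues,
                                              seed),
                                 aa = rep("G", n_residues)))
    }
    stop("failed to generate a self-avoiding coil", call. = FALSE)
  })
}

aa1_to_aa3 <- function(aa) {
  out <- suppressWarnings(bio3d::aa123(aa))
  out[is.na(out) | !nzchar(out)] <- "UNK"
  out
}

#' Write a CA trace as a minimal PDB file
#'
#' Emits CA-only ATOM records (sequential residue numbering, chain A,
#' occupancy 1.00, B-factor 0.00) readable by [read_structure()].
#'
#' @param structure a [protein_structure()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  assert_structure(structure)
  n <- n_residues(structure)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(structure$xyz)),
                   resno = seq_len(n),
                   resid = aa1_to_aa3(structure$aa),
                   chain = rep("A", n),
                   elety = rep("CA", n),
                   o = rep(1.00, n),
                   b = rep(0.00, n))
  invisible(path)
}
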