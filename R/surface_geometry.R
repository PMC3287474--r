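# Step 1 of the pipeline: per-atom SASA, the surface set S, the expanded
# convex-hull set Q, and the cleft set S \ Q.

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with a deterministic golden-spiral test-point lattice on
#' each atom's probe-expanded sphere, so results are bit-reproducible without
#' any random seed. The lattice is oriented in a per-atom frame built from
#' the two nearest neighbouring atoms, which co-rotates with the structure:
#' areas are therefore invariant under rigid motion of the input (to
#' floating-point precision), not merely under translation. Only atoms
#' within `r_i + r_j + 2*probe` of atom i can occlude its test points.
#'
#' @param atoms Atom data frame with radii assigned (see [assign_radii()]).
#' @param probe Probe radius in Angstrom (water: 1.4).
#' @param n_points Number of lattice points per atom (>= 100).
#' @return An object of class `sasa_result`: list with `area` (named numeric,
#'   names are atom serials, values in A^2), `probe`, `n_points`.
#' @export
compute_sasa <- function(atoms, probe = 1.4, n_points = 960L) {
  if (nrow(atoms) == 0) cp_stop("no atoms for SASA", "parameter_error")
  if (probe <= 0) cp_stop("probe radius must be positive", "parameter_error")
  if (n_points < 100) cp_stop("n_points must be at least 100", "parameter_error")
  if (any(is.na(atoms$radius) | atoms$radius <= 0))
    cp_stop("atoms need positive radii; run assign_radii() first", "parameter_error")
  a <- sasa_cpp(as.matrix(atoms[, c("x", "y", "z")]), atoms$radius,
                probe, as.integer(n_points))
  names(a) <- as.character(atoms$serial)
  structure(list(area = a, probe = probe, n_points = as.integer(n_points)),
            class = "sasa_result")
}

#' Surface atom set (Set S)
#'
#' Atoms whose SASA is strictly greater than the threshold (default 1 A^2)
#' are considered surface atoms.
#'
#' @param sasa A `sasa_result` from [compute_sasa()].
#' @param threshold Area threshold in A^2.
#' @return Integer vector of atom serials (sorted).
#' @export
surface_set <- function(sasa, threshold = 1.0) {
  if (threshold < 0) cp_stop("threshold must be non-negative", "parameter_error")
  sort(as.integer(names(sasa$area)[sasa$area > threshold]))
}

#' Convex hull vertex atoms
#'
#' Atoms whose centres are vertices of the 3-D convex hull of all atom
#' centres (the structure's outermost atoms).
#'
#' @param atoms Atom data frame (>= 4 atoms, not all coplanar).
#' @return Integer vector of atom serials (sorted).
#' @export
convex_hull_vertices <- function(atoms) {
  if (nrow(atoms) < 4)
    cp_stop("convex hull needs at least 4 atoms", "geometry_error")
  idx <- tryCatch(hull_vertices_cpp(as.matrix(atoms[, c("x", "y", "z")])),
                  error = function(e) cp_stop(conditionMessage(e), "geometry_error"))
  sort(as.integer(atoms$serial[idx]))
}

#' Expanded convex-hull set (Set Q)
#'
#' The hull vertex atoms plus every atom whose centre lies within
#' `expand_dist` (inclusive) of any hull vertex atom centre.
#'
#' @param hull Integer vector of hull vertex atom serials.
#' @param atoms Atom data frame containing (at least) the hull atoms.
#' @param expand_dist Expansion distance in Angstrom (default 6.5).
#' @return Integer vector of atom serials (sorted).
#' @export
expand_hull <- function(hull, atoms, expand_dist = 6.5) {
  if (expand_dist < 0) cp_stop("expand_dist must be non-negative", "parameter_error")
  if (!all(hull %in% atoms$serial))
    cp_stop("hull serials must be a subset of the atom set", "parameter_error")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  hxyz <- xyz[atoms$serial %in% hull, , drop = FALSE]
  # min squared distance from every atom to the hull vertex atoms
  d2min <- rep(Inf, nrow(xyz))
  for (k in seq_len(nrow(hxyz))) {
    d2 <- (xyz[, 1] - hxyz[k, 1])^2 + (xyz[, 2] - hxyz[k, 2])^2 +
      (xyz[, 3] - hxyz[k, 3])^2
    d2min <- pmin(d2min, d2)
  }
  sort(as.integer(atoms$serial[d2min <= expand_dist^2]))
}

#' Cleft atom set (S minus Q)
#'
#' Surface atoms that are not part of the expanded convex-hull set: atoms
#' lining concave regions of the protein surface.
#'
#' @param set_s Surface atom serials.
#' @param set_q Expanded-hull atom serials.
#' @return Integer vector of atom serials (sorted).
#' @export
cleft_atoms <- function(set_s, set_q) {
  sort(setdiff(as.integer(set_s), as.integer(set_q)))
}

#' Compute all Step-1 atom sets at once
#'
#' Convenience wrapper running SASA, surface set, hull, expansion and cleft
#' on the protein atoms of a complex.
#'
#' @param atoms Protein atom data frame with radii assigned.
#' @param config A [run_config()].
#' @return List with `sasa`, `set_s`, `hull`, `set_q`, `cleft`.
#' @export
atom_sets <- function(atoms, config = run_config()) {
  sasa <- compute_sasa(atoms, probe = config$sasa_probe,
                       n_points = config$sasa_points)
  set_s <- surface_set(sasa, threshold = config$sasa_threshold)
  hull <- convex_hull_vertices(atoms)
  set_q <- expand_hull(hull, atoms, expand_dist = config$expand_dist)
  list(sasa = sasa, set_s = set_s, hull = hull, set_q = set_q,
       cleft = cleft_atoms(set_s, set_q))
}

#' Dump per-atom SASA as TSV
#'
#' Columns: serial, res_key, area. Useful for cross-checking against external
#' SASA tools.
#'
#' @param atoms Atom data frame.
#' @param sasa Matching `sasa_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sasa_tsv <- function(atoms, sasa, path) {
  d <- data.frame(serial = atoms$serial, res_key = atoms$res_key,
                  area = unname(sasa$area[as.character(atoms$serial)]))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
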