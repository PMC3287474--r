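# Step 3: cluster potential atoms into candidate pockets. "Simple
# hierarchical clustering" is realised as single linkage cut at a distance
# threshold (equivalently: connected components of the <= link_dist contact
# graph), followed by iterative merging of nearby cluster centres.

# single-linkage threshold cut on a coordinate matrix; returns a list of
# row-index vectors. stats::hclust/cutree keep merges at height <= h, which
# matches the inclusive contract.
single_linkage_cut <- function(xyz, cut_dist) {
  n <- nrow(xyz)
  if (n == 0) return(list())
  if (n == 1) return(list(1L))
  memb <- stats::cutree(stats::hclust(stats::dist(xyz), method = "single"),
                        h = cut_dist)
  unname(split(seq_len(n), memb))
}

#' Cluster potential atoms by spatial distance
#'
#' Single-linkage clusters of the potential atoms cut at `link_dist`: two
#' atoms end up in the same cluster when they are connected by a chain of
#' pairwise distances each at most `link_dist`. Clusters smaller than
#' `min_pocket_atoms` are discarded.
#'
#' @param atoms Atom data frame (provides coordinates for the serials).
#' @param serials Potential atom serials (Set P).
#' @param link_dist Single-linkage cut distance in Angstrom.
#' @param min_pocket_atoms Minimum cluster size kept.
#' @return List of integer serial vectors, one per cluster; empty list when
#'   `serials` is empty (no pocket found, not an error).
#' @export
cluster_atoms <- function(atoms, serials, link_dist = 4.5,
                          min_pocket_atoms = 3L) {
  if (link_dist <= 0) cp_stop("link_dist must be positive", "parameter_error")
  serials <- as.integer(serials)
  if (!length(serials)) return(list())
  sub <- atoms[match(serials, atoms$serial), , drop = FALSE]
  comp <- single_linkage_cut(as.matrix(sub[, c("x", "y", "z")]), link_dist)
  clusters <- lapply(comp, function(i) sort(sub$serial[i]))
  keep <- vapply(clusters, length, integer(1)) >= min_pocket_atoms
  clusters[keep]
}

pocket_from_serials <- function(atoms, serials) {
  sub <- atoms[match(serials, atoms$serial), , drop = FALSE]
  structure(list(
    member_atoms = sort(as.integer(serials)),
    member_residues = sort(unique(sub$res_key)),
    center = colMeans(as.matrix(sub[, c("x", "y", "z")])),
    score = NA_real_,
    volume = NA_real_,
    rank = NA_integer_
  ), class = "pocket")
}

#' @export
print.pocket <- function(x, ...) {
  cat(sprintf("<pocket> %d atoms / %d residues, centre (%.2f, %.2f, %.2f)%s\n",
              length(x$member_atoms), length(x$member_residues),
              x$center[1], x$center[2], x$center[3],
              if (!is.na(x$rank)) sprintf(", rank %d score %.1f", x$rank, x$score) else ""))
  invisible(x)
}

#' Merge clusters with nearby geometric centres into pockets
#'
#' Clusters whose geometric centres lie within `merge_dist` (single linkage
#' over centres) are united; the merged pocket's centre is recomputed as the
#' mean over all member atoms. Because recomputation can bring new centre
#' pairs within range, merging is iterated to a fixpoint, after which all
#' pairwise pocket-centre distances exceed `merge_dist`.
#'
#' @param clusters List of atom-serial vectors (disjoint).
#' @param atoms Atom data frame.
#' @param merge_dist Centre-merge distance in Angstrom (default 8).
#' @return List of `pocket` objects, ordered by (size desc, smallest member
#'   serial asc) so downstream output is deterministic.
#' @export
merge_centers <- function(clusters, atoms, merge_dist = 8.0) {
  if (merge_dist <= 0) cp_stop("merge_dist must be positive", "parameter_error")
  groups <- clusters
  repeat {
    if (length(groups) < 2) break
    centers <- t(vapply(groups, function(s) {
      sub <- atoms[match(s, atoms$serial), , drop = FALSE]
      colMeans(as.matrix(sub[, c("x", "y", "z")]))
    }, numeric(3)))
    if (min(stats::dist(centers)) > merge_dist) break
    comp <- single_linkage_cut(centers, merge_dist)
    groups <- lapply(comp, function(i) sort(unique(unlist(groups[i]))))
  }
  pockets <- lapply(groups, function(s) pocket_from_serials(atoms, s))
  ord <- order(-vapply(pockets, function(p) length(p$member_atoms), integer(1)),
               vapply(pockets, function(p) min(p$member_atoms), integer(1)))
  pockets[ord]
}

#' Predict candidate binding pockets for a complex
#'
#' Full pipeline composition: SASA surface set, expanded convex hull, cleft
#' atoms, conservation filter (skipped when `config$conservation_cutoff` is
#' `NA` or `cmap` is `NULL`, in which case P = cleft), spatial clustering and
#' centre merging. Deterministic for fixed inputs and parameters.
#'
#' The returned list carries an attribute `"stats"` with the intermediate
#' set sizes (`n_S`, `n_Q`, `n_cleft`, `n_C`, `n_P`, `n_clusters`,
#' `n_pockets`) so runs are auditable.
#'
#' @param complex A `protein_complex` from [read_pdb()].
#' @param cmap A `conservation_map`, or `NULL` to skip conservation.
#' @param config A [run_config()].
#' @return List of unranked `pocket` objects (possibly empty).
#' @export
predict_pockets <- function(complex, cmap = NULL, config = run_config()) {
  atoms <- complex$protein
  sets <- atom_sets(atoms, config)
  use_cons <- !is.null(cmap) && !is.na(config$conservation_cutoff)
  if (use_cons) {
    set_c <- conserved_atom_set(atoms, cmap, cutoff = config$conservation_cutoff)
    set_p <- potential_atoms(sets$cleft, set_c)
  } else {
    set_c <- integer(0)
    set_p <- sets$cleft
  }
  clusters <- cluster_atoms(atoms, set_p, link_dist = config$atom_link_dist,
                            min_pocket_atoms = config$min_pocket_atoms)
  pockets <- merge_centers(clusters, atoms, merge_dist = config$center_merge_dist)
  attr(pockets, "stats") <- c(n_S = length(sets$set_s), n_Q = length(sets$set_q),
                              n_cleft = length(sets$cleft),
                              n_C = if (use_cons) length(set_c) else NA_integer_,
                              n_P = length(set_p),
                              n_clusters = length(clusters),
                              n_pockets = length(pockets))
  pockets
}
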