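# Ranking candidate pockets: by summed residue conservation grades (the
# default) or by an estimated pocket volume.

#' Conservation score of a pocket
#'
#' Sum (or mean) of the integer conservation grades over the pocket's
#' distinct member residues. Each residue counts once no matter how many of
#' its atoms are pocket members; residues without a grade contribute 0.
#'
#' @param pocket A `pocket`.
#' @param cmap A `conservation_map`, or `NULL` (score 0).
#' @param aggregate `"sum"` (default) or `"mean"`.
#' @return A single number.
#' @export
conservation_score <- function(pocket, cmap, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  if (is.null(cmap)) return(0)
  g <- unname(cmap[pocket$member_residues])
  g[is.na(g)] <- 0L
  if (aggregate == "sum") sum(g) else mean(g)
}

#' Pocket volume estimate
#'
#' Volume of the union of probe-inflated spheres (radius `r_vdw + probe`)
#' centred on the pocket's member atoms, estimated by counting voxel centres
#' on a deterministic axis-aligned grid whose corners lie at global multiples
#' of `grid_step`. Converges to the analytic union volume as the step shrinks;
#' the global anchoring makes the estimate translation-consistent to within
#' one voxel shell.
#'
#' @param pocket A `pocket`.
#' @param atoms Atom data frame with radii (provides member coordinates).
#' @param grid_step Voxel edge length in Angstrom.
#' @param probe Inflation radius added to each van der Waals radius.
#' @return Volume in A^3.
#' @export
pocket_volume <- function(pocket, atoms, grid_step = 1.0, probe = 1.4) {
  if (grid_step <= 0) cp_stop("grid_step must be positive", "parameter_error")
  sub <- atoms[match(pocket$member_atoms, atoms$serial), , drop = FALSE]
  union_sphere_volume_cpp(as.matrix(sub[, c("x", "y", "z")]),
                          sub$radius + probe, grid_step)
}

#' Rank pockets into a candidate list
#'
#' Sorts pockets by the chosen score, descending. Ties are broken by more
#' member atoms first, then by smaller minimum member serial, so the ranking
#' is a deterministic permutation of the input.
#'
#' @param pockets List of `pocket` objects.
#' @param method `"conservation"` or `"volume"`.
#' @param cmap A `conservation_map` (needed for `"conservation"`).
#' @param atoms Atom data frame (needed for `"volume"`).
#' @param config A [run_config()] supplying `volume_grid`, `sasa_probe` and
#'   `aggregate`.
#' @param structure_id Identifier carried into the result.
#' @return An object of class `ranked_prediction`: list with `pockets`
#'   (ranked, each with `score` and `rank` filled), `method`, `structure_id`.
#' @export
rank_pockets <- function(pockets, method = c("conservation", "volume"),
                         cmap = NULL, atoms = NULL, config = run_config(),
                         structure_id = "") {
  method <- match.arg(method)
  scores <- vapply(pockets, function(p) {
    if (method == "conservation") {
      conservation_score(p, cmap, aggregate = config$aggregate)
    } else {
      if (is.null(atoms)) cp_stop("volume ranking needs the atom table", "parameter_error")
      pocket_volume(p, atoms, grid_step = config$volume_grid,
                    probe = config$sasa_probe)
    }
  }, numeric(1))
  sizes <- vapply(pockets, function(p) length(p$member_atoms), integer(1))
  minser <- vapply(pockets, function(p) min(p$member_atoms), integer(1))
  ord <- order(-scores, -sizes, minser)
  ranked <- pockets[ord]
  for (i in seq_along(ranked)) {
    ranked[[i]]$score <- scores[ord][i]
    ranked[[i]]$rank <- i
  }
  structure(list(pockets = ranked, method = method, structure_id = structure_id),
            class = "ranked_prediction")
}

#' @export
print.ranked_prediction <- function(x, ...) {
  cat(sprintf("<ranked_prediction> %s: %d pocket(s) ranked by %s\n",
              x$structure_id, length(x$pockets), x$method))
  for (p in x$pockets[seq_len(min(5, length(x$pockets)))]) print(p)
  invisible(x)
}

#' Tabulate a ranked prediction
#'
#' @param prediction A `ranked_prediction`.
#' @return Data frame with one row per pocket: rank, score, centre
#'   coordinates, sizes, and a comma-separated member residue list.
#' @export
prediction_table <- function(prediction) {
  ps <- prediction$pockets
  data.frame(
    rank = vapply(ps, function(p) p$rank, integer(1)),
    method = rep(prediction$method, length(ps)),
    score = vapply(ps, function(p) p$score, numeric(1)),
    center_x = vapply(ps, function(p) p$center[1], numeric(1)),
    center_y = vapply(ps, function(p) p$center[2], numeric(1)),
    center_z = vapply(ps, function(p) p$center[3], numeric(1)),
    n_atoms = vapply(ps, function(p) length(p$member_atoms), integer(1)),
    n_residues = vapply(ps, function(p) length(p$member_residues), integer(1)),
    residues = vapply(ps, function(p) paste(p$member_residues, collapse = ","),
                      character(1)),
    stringsAsFactors = FALSE
  )
}
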