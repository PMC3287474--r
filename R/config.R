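#' Pipeline parameters
#'
#' Bundles every tunable threshold of the prediction pipeline. Defaults follow
#' the published procedure where it states a value (surface-area threshold
#' 1 A^2, hull expansion 6.5 A, conservation grade cutoff 7, centre merge 8 A,
#' hit cutoff 4 A); the remaining defaults are this implementation's own
#' documented choices (see the methods vignette).
#'
#' @param sasa_probe Solvent probe radius in Angstrom (water, 1.4).
#' @param sasa_points Test points per atom for the Shrake-Rupley lattice.
#' @param sasa_threshold Surface-set threshold in A^2; atoms with SASA
#'   strictly greater than this form Set S.
#' @param expand_dist Convex-hull expansion distance in Angstrom (Set Q).
#' @param conservation_cutoff Minimum ConSurf colour grade (1-9) a residue
#'   needs for its atoms to enter Set C, or `NA` to skip the conservation
#'   filter entirely (then P = cleft).
#' @param atom_link_dist Single-linkage cut distance for clustering potential
#'   atoms, in Angstrom.
#' @param center_merge_dist Distance below which cluster centres are merged
#'   into one pocket, in Angstrom.
#' @param min_pocket_atoms Clusters smaller than this are discarded.
#' @param rank_method `"conservation"` or `"volume"`.
#' @param hit_cutoff PocketPicker hit criterion distance in Angstrom.
#' @param volume_grid Voxel edge length for pocket volume estimation, Angstrom.
#' @param aggregate How residue grades combine into a pocket conservation
#'   score: `"sum"` (default) or `"mean"`.
#' @param radius_set Van der Waals radius table name (see [assign_radii()]).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(sasa_probe = 1.4,
                       sasa_points = 960L,
                       sasa_threshold = 1.0,
                       expand_dist = 6.5,
                       conservation_cutoff = 7L,
                       atom_link_dist = 4.5,
                       center_merge_dist = 8.0,
                       min_pocket_atoms = 3L,
                       rank_method = c("conservation", "volume"),
                       hit_cutoff = 4.0,
                       volume_grid = 1.0,
                       aggregate = c("sum", "mean"),
                       radius_set = "chothia") {
  rank_method <- match.arg(rank_method)
  aggregate <- match.arg(aggregate)
  if (sasa_probe <= 0) cp_stop("sasa_probe must be positive", "parameter_error")
  if (sasa_points < 100) cp_stop("sasa_points must be at least 100", "parameter_error")
  if (sasa_threshold < 0) cp_stop("sasa_threshold must be non-negative", "parameter_error")
  if (expand_dist < 0) cp_stop("expand_dist must be non-negative", "parameter_error")
  if (!is.na(conservation_cutoff) &&
      (conservation_cutoff < 1 || conservation_cutoff > 9))
    cp_stop("conservation_cutoff must be in [1, 9] or NA", "parameter_error")
  if (atom_link_dist <= 0 || center_merge_dist <= 0)
    cp_stop("clustering distances must be positive", "parameter_error")
  if (min_pocket_atoms < 1) cp_stop("min_pocket_atoms must be >= 1", "parameter_error")
  if (hit_cutoff <= 0) cp_stop("hit_cutoff must be positive", "parameter_error")
  if (volume_grid <= 0) cp_stop("volume_grid must be positive", "parameter_error")
  structure(list(
    sasa_probe = sasa_probe,
    sasa_points = as.integer(sasa_points),
    sasa_threshold = sasa_threshold,
    expand_dist = expand_dist,
    conservation_cutoff = if (is.na(conservation_cutoff)) NA_integer_ else as.integer(conservation_cutoff),
    atom_link_dist = atom_link_dist,
    center_merge_dist = center_merge_dist,
    min_pocket_atoms = as.integer(min_pocket_atoms),
    rank_method = rank_method,
    hit_cutoff = hit_cutoff,
    volume_grid = volume_grid,
    aggregate = aggregate,
    radius_set = radius_set
  ), class = "run_config")
}

# one-line-per-parameter header block embedded in every report for provenance
config_header <- function(config) {
  vals <- vapply(config, function(v) {
    if (length(v) == 1 && is.na(v)) "none" else as.character(v)
  }, character(1))
  paste0("# ", names(config), " = ", vals)
}
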