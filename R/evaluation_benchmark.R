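# Evaluation under the PocketPicker criterion: a ranked pocket is a hit when
# its geometric centre is within 4 A (inclusive) of any atom of any ligand;
# TOP-N success rates aggregate hits over a dataset.

#' PocketPicker hit criterion
#'
#' A predicted centre is a hit when its minimum distance to any ligand atom
#' centre is at most `cutoff` (default 4 A, inclusive).
#'
#' @param center Numeric 3-vector.
#' @param ligand_atoms Atom data frame of ligand atoms (non-empty).
#' @param cutoff Distance cutoff in Angstrom.
#' @return `TRUE` or `FALSE`.
#' @export
is_hit <- function(center, ligand_atoms, cutoff = 4.0) {
  if (nrow(ligand_atoms) == 0)
    cp_stop("hit test needs at least one ligand atom", "evaluation_error")
  d2 <- (ligand_atoms$x - center[1])^2 + (ligand_atoms$y - center[2])^2 +
    (ligand_atoms$z - center[3])^2
  min(d2) <= cutoff^2
}

#' Evaluate a ranked prediction against the bound ligands
#'
#' Each ranked pocket centre is tested against every ligand group of the
#' complex; a rank is a hit when any group satisfies [is_hit()].
#'
#' @param prediction A `ranked_prediction`.
#' @param complex The matching `protein_complex` (ligands put back).
#' @param cutoff Hit distance in Angstrom.
#' @return An object of class `hit_record`: list with `structure_id`,
#'   `ranks_hit` (integer vector), `top1_hit`, `top3_hit`.
#' @export
evaluate_structure <- function(prediction, complex, cutoff = 4.0) {
  if (nrow(complex$ligands) == 0)
    cp_stop(sprintf("structure %s has no ligand to evaluate against",
                    complex$source_id), "evaluation_error")
  groups <- split(complex$ligands, complex$ligands$ligand_id)
  ranks_hit <- integer(0)
  for (p in prediction$pockets) {
    hit <- any(vapply(groups, function(g) is_hit(p$center, g, cutoff), logical(1)))
    if (hit) ranks_hit <- c(ranks_hit, p$rank)
  }
  structure(list(structure_id = prediction$structure_id,
                 ranks_hit = sort(ranks_hit),
                 top1_hit = length(ranks_hit) > 0 && min(ranks_hit) <= 1,
                 top3_hit = length(ranks_hit) > 0 && min(ranks_hit) <= 3),
            class = "hit_record")
}

#' Read a dataset manifest
#'
#' A manifest is a TSV with columns `structure_id`, `pdb_path`,
#' `grades_path`; relative paths are resolved against the manifest's
#' directory.
#'
#' @param path Manifest file path.
#' @return Data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    cp_stop(sprintf("manifest not found: %s", path), "input_error")
  m <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("structure_id", "pdb_path", "grades_path")
  if (!all(need %in% names(m)))
    cp_stop(sprintf("manifest must have columns %s", paste(need, collapse = ", ")),
            "format_error")
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(nzchar(p) & !grepl("^/", p), file.path(base, p), p)
  m$pdb_path <- fix(m$pdb_path)
  m$grades_path <- fix(m$grades_path)
  m
}

predict_and_rank <- function(pdb_path, grades_path, config, method,
                             structure_id) {
  complex <- read_pdb(pdb_path, radius_set = config$radius_set,
                      source_id = structure_id)
  cmap <- NULL
  if (!is.na(config$conservation_cutoff) && nzchar(grades_path %||% ""))
    cmap <- suppressWarnings(parse_grades(grades_path))
  pockets <- predict_pockets(complex, cmap, config)
  prediction <- rank_pockets(pockets, method = method, cmap = cmap,
                             atoms = complex$protein, config = config,
                             structure_id = structure_id)
  list(complex = complex, cmap = cmap, prediction = prediction,
       stats = attr(pockets, "stats"))
}

#' Benchmark the predictor over a dataset
#'
#' Runs the full pipeline on every manifest entry and aggregates TOP-1 and
#' TOP-3 success rates. A structure on which prediction ran but produced no
#' pocket counts as a miss (it stays in the denominator); a structure whose
#' inputs could not be processed at all (unreadable file, no ligand) is
#' excluded and reported as skipped, so denominators stay auditable.
#'
#' @param manifest Data frame from [read_manifest()], or a manifest path.
#' @param config A [run_config()].
#' @param method Ranking method, `"conservation"` or `"volume"`.
#' @return Object of class `benchmark_result`: list with `top1_rate`,
#'   `top3_rate`, `n_evaluated`, `n_skipped`, and a `per_structure` data
#'   frame (status, hit flags, intermediate set sizes per structure).
#' @export
benchmark <- function(manifest, config = run_config(),
                      method = config$rank_method) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (nrow(manifest) < 1) cp_stop("empty manifest", "evaluation_error")
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$structure_id[i]
    res <- tryCatch({
      r <- predict_and_rank(manifest$pdb_path[i], manifest$grades_path[i],
                            config, method, id)
      hr <- evaluate_structure(r$prediction, r$complex,
                               cutoff = config$hit_cutoff)
      data.frame(structure_id = id, status = "evaluated",
                 n_pockets = length(r$prediction$pockets),
                 n_P = unname(r$stats["n_P"]),
                 best_rank_hit = if (length(hr$ranks_hit)) min(hr$ranks_hit) else NA_integer_,
                 top1_hit = hr$top1_hit, top3_hit = hr$top3_hit,
                 reason = "", stringsAsFactors = FALSE)
    }, conspocket_error = function(e) {
      data.frame(structure_id = id, status = "skipped",
                 n_pockets = NA_integer_, n_P = NA_integer_,
                 best_rank_hit = NA_integer_,
                 top1_hit = NA, top3_hit = NA,
                 reason = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  per <- do.call(rbind, rows)
  ev <- per[per$status == "evaluated", , drop = FALSE]
  if (nrow(ev) == 0) cp_stop("all structures were skipped", "evaluation_error")
  structure(list(
    top1_rate = mean(ev$top1_hit),
    top3_rate = mean(ev$top3_hit),
    n_evaluated = nrow(ev),
    n_skipped = sum(per$status == "skipped"),
    method = method,
    per_structure = per
  ), class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d evaluated (%d skipped), ranking by %s\n",
              x$n_evaluated, x$n_skipped, x$method))
  cat(sprintf("  TOP1 %.1f%%  TOP3 %.1f%%\n", 100 * x$top1_rate, 100 * x$top3_rate))
  invisible(x)
}

#' Two-factor parameter sweep
#'
#' Full factorial sweep over hull expansion distances and conservation grade
#' cutoffs (use `NA` for the no-conservation control, where P = cleft). Cells
#' in which one or more structures yielded zero potential atoms are flagged
#' via `n_empty_P`.
#'
#' @param manifest Data frame from [read_manifest()], or a manifest path.
#' @param expand_dists Numeric vector of expansion distances in Angstrom.
#' @param cutoffs Integer vector of grade cutoffs; `NA` entries disable the
#'   conservation filter.
#' @param config Base [run_config()]; each cell overrides `expand_dist` and
#'   `conservation_cutoff`.
#' @param method Ranking method for all cells.
#' @return Data frame in long format: `expand_dist`, `cutoff` (`"none"` for
#'   `NA`), `top1_rate`, `top3_rate`, `n_evaluated`, `n_skipped`,
#'   `n_empty_P`.
#' @export
parameter_sweep <- function(manifest, expand_dists, cutoffs,
                            config = run_config(),
                            method = config$rank_method) {
  if (!length(expand_dists) || !length(cutoffs))
    cp_stop("sweep grids must be non-empty", "parameter_error")
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  out <- list()
  for (ed in expand_dists) {
    for (cc in cutoffs) {
      cfg <- config
      cfg$expand_dist <- ed
      cfg$conservation_cutoff <- if (is.na(cc)) NA_integer_ else as.integer(cc)
      b <- benchmark(manifest, cfg, method = method)
      per <- b$per_structure
      out[[length(out) + 1]] <- data.frame(
        expand_dist = ed,
        cutoff = if (is.na(cc)) "none" else as.character(cc),
        top1_rate = b$top1_rate, top3_rate = b$top3_rate,
        n_evaluated = b$n_evaluated, n_skipped = b$n_skipped,
        n_empty_P = sum(per$n_P == 0, na.rm = TRUE),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
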