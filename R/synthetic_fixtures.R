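# Deterministic toy structures with planted pockets: a jittered-grid ball of
# carbon pseudo-atoms, cylindrical invaginations carved along chosen
# directions, a small ligand seated in each real pocket, and per-residue
# conservation grades enriched on pocket linings. Everything derives from an
# explicit seed, so fixtures are reproducible byte for byte.

DEFAULT_BACKGROUND_GRADES <- c(0.14, 0.14, 0.14, 0.14, 0.14, 0.10, 0.08, 0.07, 0.05)

#' Specification of a synthetic pocketed structure
#'
#' @param shell_radius Radius of the pseudo-protein ball in Angstrom.
#' @param atom_spacing Grid spacing of the pseudo-atoms in Angstrom.
#' @param pockets List of pockets, each a list with `direction` (3-vector,
#'   need not be unit), `mouth_radius` and `depth` in Angstrom, and an
#'   optional `decoy` flag. A decoy pocket is carved like a real one but
#'   carries no ligand and gets no conservation enrichment — a purely
#'   geometric cleft that only the conservation filter can reject.
#' @param conserved_fraction_in_pocket Probability that a pocket-lining
#'   residue of a real pocket receives a conserved grade (7-9).
#' @param background_grade_distribution Probabilities of grades 1..9 for all
#'   other residues; must sum to 1.
#' @param atoms_per_residue Pseudo-atoms grouped per residue (1 keeps the
#'   residue-grade mapping trivial; 3 exercises residue-level aggregation).
#' @param jitter Grid jitter as a fraction of `atom_spacing`.
#' @param seed Integer seed controlling every random draw.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(shell_radius = 18,
                         atom_spacing = 3.0,
                         pockets = list(list(direction = c(1, 0, 0),
                                             mouth_radius = 7.0, depth = 10.0)),
                         conserved_fraction_in_pocket = 0.9,
                         background_grade_distribution = DEFAULT_BACKGROUND_GRADES,
                         atoms_per_residue = 1L,
                         jitter = 0.25,
                         seed = 1L) {
  if (abs(sum(background_grade_distribution) - 1) > 1e-8 ||
      length(background_grade_distribution) != 9)
    cp_stop("background grade distribution needs 9 probabilities summing to 1",
            "spec_error")
  for (p in pockets) {
    if (p$depth >= shell_radius)
      cp_stop("pocket depth must be smaller than the shell radius", "spec_error")
    if (p$mouth_radius <= 0 || p$depth <= 0)
      cp_stop("pocket mouth and depth must be positive", "spec_error")
  }
  # pockets must not overlap: angular separation above the sum of the
  # half-angles their mouths subtend at the centre
  if (length(pockets) > 1) {
    dirs <- lapply(pockets, function(p) p$direction / sqrt(sum(p$direction^2)))
    for (i in seq_along(pockets)) for (j in seq_len(i - 1)) {
      ang <- acos(max(-1, min(1, sum(dirs[[i]] * dirs[[j]]))))
      lim <- 2 * asin(min(1, max(pockets[[i]]$mouth_radius,
                                 pockets[[j]]$mouth_radius) / shell_radius))
      if (ang <= lim)
        cp_stop("pocket directions overlap (angular separation too small)",
                "spec_error")
    }
  }
  structure(list(shell_radius = shell_radius, atom_spacing = atom_spacing,
                 pockets = pockets,
                 conserved_fraction_in_pocket = conserved_fraction_in_pocket,
                 background_grade_distribution = background_grade_distribution,
                 atoms_per_residue = as.integer(atoms_per_residue),
                 jitter = jitter, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a pocketed pseudo-protein
#'
#' Builds the structure a [fixture_spec()] describes: carbon pseudo-atoms on
#' a jittered cubic grid clipped to a ball, one carved invagination per
#' pocket, a 3-8 atom ligand at each real pocket's seat, and a conservation
#' map enriched (grades 7-9 with probability
#' `conserved_fraction_in_pocket`) on pocket-lining residues and drawn from
#' the background distribution elsewhere.
#'
#' @param spec A [fixture_spec()].
#' @return List with `complex` (a `protein_complex`), `cmap` (a
#'   `conservation_map`), `ground_truth` (list of real-pocket ligand
#'   centroids), and `spec`.
#' @export
make_pocketed_structure <- function(spec) {
  withr::with_seed(spec$seed, {
    R <- spec$shell_radius
    s <- spec$atom_spacing
    g <- seq(-R, R, by = s)
    grid <- as.matrix(expand.grid(x = g, y = g, z = g))
    grid <- grid + matrix(stats::runif(length(grid), -spec$jitter * s,
                                       spec$jitter * s), ncol = 3)
    grid <- grid[rowSums(grid^2) <= R^2, , drop = FALSE]

    dirs <- lapply(spec$pockets, function(p) p$direction / sqrt(sum(p$direction^2)))
    lining <- rep(FALSE, nrow(grid))
    keep <- rep(TRUE, nrow(grid))
    band <- 1.2 * s
    for (k in seq_along(spec$pockets)) {
      p <- spec$pockets[[k]]
      u <- dirs[[k]]
      proj <- grid %*% u
      perp <- sqrt(pmax(0, rowSums(grid^2) - proj^2))
      carved <- proj >= (R - p$depth) & perp <= p$mouth_radius
      keep <- keep & !carved
      lining <- lining | (proj >= (R - p$depth - band) &
                            perp <= (p$mouth_radius + band) & !carved)
    }
    coords <- grid[keep, , drop = FALSE]
    lining <- lining[keep]
    n <- nrow(coords)

    apr <- spec$atoms_per_residue
    resno <- as.integer(ceiling(seq_len(n) / apr))
    within <- ((seq_len(n) - 1L) %% apr) + 1L
    protein <- data.frame(
      serial = seq_len(n),
      name = if (apr == 1) rep("CA", n) else paste0("C", within),
      element = rep("C", n),
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      chain = rep("A", n), resno = resno, insert = rep("", n),
      resid = rep("GLY", n), occ = rep(1, n), altloc = rep("", n),
      is_hetero = rep(FALSE, n), stringsAsFactors = FALSE
    )
    protein$res_key <- residue_key(protein$chain, protein$resno, protein$insert)
    protein <- assign_radii(protein)

    # residue grades: enrichment on linings of real pockets only
    real <- !vapply(spec$pockets, function(p) isTRUE(p$decoy), logical(1))
    lining_real <- rep(FALSE, n)
    for (k in seq_along(spec$pockets)) {
      if (!real[k]) next
      u <- dirs[[k]]
      p <- spec$pockets[[k]]
      proj <- coords %*% u
      perp <- sqrt(pmax(0, rowSums(coords^2) - proj^2))
      lining_real <- lining_real | (proj >= (R - p$depth - band) &
                                      perp <= (p$mouth_radius + band))
    }
    n_res <- max(resno)
    res_lining <- vapply(seq_len(n_res),
                         function(r) any(lining_real[resno == r]), logical(1))
    grades <- integer(n_res)
    for (r in seq_len(n_res)) {
      grades[r] <- if (res_lining[r] &&
                       stats::runif(1) < spec$conserved_fraction_in_pocket) {
        sample(7:9, 1)
      } else {
        sample(1:9, 1, prob = spec$background_grade_distribution)
      }
    }
    cmap <- structure(stats::setNames(grades, residue_key("A", seq_len(n_res))),
                      class = "conservation_map")

    # one small ligand seated in each real pocket
    lig_rows <- list()
    ground_truth <- list()
    serial0 <- n
    for (k in seq_along(spec$pockets)) {
      if (!real[k]) next
      p <- spec$pockets[[k]]
      u <- dirs[[k]]
      seat <- (R - p$depth + 1.8) * u
      n_lig <- sample(3:8, 1)
      pos <- sweep(matrix(stats::runif(3 * n_lig, -1.2, 1.2), ncol = 3), 2,
                   seat, `+`)
      lig <- data.frame(
        serial = serial0 + seq_len(n_lig),
        name = paste0("C", seq_len(n_lig)),
        element = rep("C", n_lig),
        x = pos[, 1], y = pos[, 2], z = pos[, 3],
        chain = rep("L", n_lig), resno = rep(k, n_lig),
        insert = rep("", n_lig), resid = rep("LIG", n_lig),
        occ = rep(1, n_lig), altloc = rep("", n_lig),
        is_hetero = rep(TRUE, n_lig), stringsAsFactors = FALSE
      )
      lig$res_key <- residue_key(lig$chain, lig$resno, lig$insert)
      serial0 <- serial0 + n_lig
      lig_rows[[length(lig_rows) + 1]] <- lig
      ground_truth[[length(ground_truth) + 1]] <- colMeans(pos)
    }
    ligands <- if (length(lig_rows)) do.call(rbind, lig_rows) else {
      protein[0, , drop = FALSE]
    }
    if (nrow(ligands)) ligands <- assign_radii(ligands)
    ligands$ligand_id <- if (nrow(ligands)) {
      paste(ligands$resid, ligands$chain, ligands$resno, sep = "_")
    } else character(0)

    complex <- structure(list(protein = protein, ligands = ligands,
                              n_waters_removed = 0L,
                              source_id = sprintf("synthetic_seed%d", spec$seed)),
                         class = "protein_complex")
    list(complex = complex, cmap = cmap, ground_truth = ground_truth,
         spec = spec)
  })
}

#' Write a fixture to disk as PDB + grades TSV
#'
#' @param fixture Result of [make_pocketed_structure()].
#' @param dir Output directory (created if needed).
#' @param id File stem; produces `<id>.pdb` and `<id>_grades.tsv`.
#' @return Named character vector with `pdb` and `grades` paths.
#' @export
write_fixture <- function(fixture, dir, id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  atoms <- rbind(fixture$complex$protein,
                 fixture$complex$ligands[, names(fixture$complex$protein),
                                         drop = FALSE])
  pdb <- file.path(dir, paste0(id, ".pdb"))
  write_pdb_atoms(atoms, pdb)
  grades <- file.path(dir, paste0(id, "_grades.tsv"))
  keys <- strsplit(names(fixture$cmap), ":", fixed = TRUE)
  utils::write.table(
    data.frame(chain = vapply(keys, `[`, character(1), 1),
               resno = vapply(keys, `[`, character(1), 2),
               grade = as.integer(fixture$cmap)),
    grades, sep = "\t", quote = FALSE, row.names = FALSE)
  c(pdb = pdb, grades = grades)
}

# a deterministic random rotation matrix (det +1) from the current RNG stream
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a benchmark suite of synthetic fixtures
#'
#' Writes `n` fixtures with varied geometry (shell radius 18-21 A, depth
#' 10-11 A, mouth 6.5-7.5 A, 1-2 real pockets, and with probability 0.4 one
#' larger unconserved decoy cleft) plus a manifest consumable by
#' [benchmark()]. Pocket directions sit 120 degrees apart in a randomly
#' oriented plane, which keeps the carved linings of any two pockets more
#' than one linkage cut apart so clusters cannot chain between pockets.
#' Per-fixture seeds are `seed * 1000 + i`, so any single fixture can be
#' regenerated in isolation.
#'
#' @param n Number of fixtures.
#' @param dir Output directory.
#' @param seed Master seed.
#' @param base_spec A [fixture_spec()] supplying spacing, conservation and
#'   grade-distribution settings (geometry fields are re-drawn per fixture).
#' @return Path of the written manifest TSV.
#' @export
make_suite <- function(n, dir, seed = 1L,
                       base_spec = fixture_spec()) {
  if (n < 1) cp_stop("suite size must be at least 1", "parameter_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    si <- as.integer(seed) * 1000L + i
    geom <- withr::with_seed(si, {
      rot <- random_rotation()
      axes <- lapply(0:2, function(k)
        as.numeric(rot %*% c(cos(2 * pi * k / 3), sin(2 * pi * k / 3), 0)))
      n_real <- sample(1:2, 1)
      pockets <- lapply(seq_len(n_real), function(k) {
        list(direction = axes[[k]],
             mouth_radius = stats::runif(1, 6.5, 7.5),
             depth = stats::runif(1, 10, 11))
      })
      if (stats::runif(1) < 0.4) {
        pockets[[length(pockets) + 1]] <-
          list(direction = axes[[3]],
               mouth_radius = stats::runif(1, 7.5, 8.5),
               depth = stats::runif(1, 10, 11), decoy = TRUE)
      }
      list(shell_radius = sample(18:21, 1), pockets = pockets)
    })
    spec <- fixture_spec(
      shell_radius = geom$shell_radius,
      atom_spacing = base_spec$atom_spacing,
      pockets = geom$pockets,
      conserved_fraction_in_pocket = base_spec$conserved_fraction_in_pocket,
      background_grade_distribution = base_spec$background_grade_distribution,
      atoms_per_residue = base_spec$atoms_per_residue,
      jitter = base_spec$jitter,
      seed = si
    )
    id <- sprintf("fix_%03d", i)
    write_fixture(make_pocketed_structure(spec), dir, id)
    rows[[i]] <- data.frame(structure_id = id,
                            pdb_path = paste0(id, ".pdb"),
                            grades_path = paste0(id, "_grades.tsv"),
                            stringsAsFactors = FALSE)
  }
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest
}
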