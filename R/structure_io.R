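# Reading/writing PDB structures and splitting them into protein, ligand(s)
# and discarded solvent. Parsing itself is delegated to bio3d; the splitting,
# altloc resolution, element inference and error contracts live here.

WATER_RESNAMES <- c("HOH", "WAT", "DOD")

# united-heavy-atom radii (Chothia 1976) as the default set; Bondi 1964 as an
# alternative. Values in Angstrom.
RADIUS_SETS <- list(
  chothia = c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.90),
  bondi = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, F = 1.47,
            CL = 1.75, BR = 1.85, I = 1.98, H = 1.20)
)

# elements recognised when inferring from HETATM atom names
TWO_LETTER_ELEMENTS <- c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "CA", "CU",
                         "NI", "CO", "CD", "HG", "SE", "SI", "AL", "LI")

infer_element <- function(name, resid, is_hetero) {
  name <- toupper(gsub("[^A-Za-z]", "", name))
  resid <- toupper(trimws(resid))
  el <- substr(name, 1, 1)
  # monoatomic ions and metals: the residue name repeats the atom name
  two <- substr(name, 1, 2)
  hit <- is_hetero & nchar(name) >= 2 & two %in% TWO_LETTER_ELEMENTS &
    (resid == name | resid == two)
  el[hit] <- two[hit]
  el
}

#' Assign van der Waals radii to atoms
#'
#' Sets the `radius` column from a published radius table. Elements missing
#' from the table receive `default_radius` with a warning.
#'
#' @param atoms An atom data frame (as found in a [read_pdb()] result).
#' @param radius_set `"chothia"` (united heavy atoms, default) or `"bondi"`.
#' @param default_radius Radius in Angstrom for elements not in the table.
#' @return `atoms` with its `radius` column filled in.
#' @export
assign_radii <- function(atoms, radius_set = "chothia", default_radius = 1.8) {
  if (!radius_set %in% names(RADIUS_SETS))
    cp_stop(sprintf("unknown radius set '%s'", radius_set), "config_error")
  tab <- RADIUS_SETS[[radius_set]]
  el <- toupper(atoms$element)
  if (any(el == "" | is.na(el)))
    cp_stop("every atom needs an element before radius assignment", "format_error")
  r <- unname(tab[el])
  unknown <- is.na(r)
  if (any(unknown)) {
    cp_warn(sprintf("no %s radius for element(s) %s; using default %.2f A",
                    radius_set, paste(sort(unique(el[unknown])), collapse = ", "),
                    default_radius))
    r[unknown] <- default_radius
  }
  atoms$radius <- r
  atoms
}

# pre-scan ATOM/HETATM records so malformed coordinates are reported with
# their line number (bio3d would silently coerce to NA)
validate_coordinate_fields <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(rec)
  for (i in idx) {
    fields <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    num <- suppressWarnings(as.numeric(fields))
    if (any(is.na(num)))
      cp_stop(sprintf("unparseable coordinate field on line %d: '%s'",
                      i, trimws(lines[i])), "format_error")
  }
  invisible(idx)
}

# keep one conformer per (residue, atom name): highest occupancy, ties by
# lexicographically smallest altloc (so 'A' wins)
resolve_altlocs <- function(at) {
  grp <- paste(at$chain, at$resno, at$insert, at$elety, at$type, sep = "\r")
  if (!anyDuplicated(grp)) return(at)
  ord <- order(grp, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at[!duplicated(grp[ord]), , drop = FALSE]
}

#' Read a PDB file into a protein/ligand complex
#'
#' Parses a PDB file (first MODEL only), drops hydrogens and waters, resolves
#' alternate locations to a single conformer, and splits the remaining heavy
#' atoms into polymer (`ATOM`) and ligand (`HETATM`) sets. Ligand atoms are
#' grouped into ligand instances by (residue name, chain, residue number);
#' ions and cofactors count as ligands unless listed in `ligand_exclude`.
#'
#' @param path Path to a PDB file.
#' @param ligand_exclude Character vector of HETATM residue names to drop
#'   entirely (e.g. `c("SO4", "GOL")`). Empty by default.
#' @param radius_set Van der Waals radius table used for the atoms.
#' @param source_id Identifier for the structure; defaults to the file name
#'   without extension.
#' @return An object of class `protein_complex`: a list with `protein`
#'   (atom data frame), `ligands` (atom data frame with a `ligand_id`
#'   column, zero rows if none), `n_waters_removed`, and `source_id`.
#' @export
read_pdb <- function(path, ligand_exclude = character(), radius_set = "chothia",
                     source_id = NULL) {
  if (!file.exists(path))
    cp_stop(sprintf("PDB file not found: %s", path), "input_error")
  lines <- readLines(path, warn = FALSE)
  # first MODEL only
  mdl <- grep("^ENDMDL", lines)
  if (length(mdl)) lines <- lines[seq_len(mdl[1])]
  validate_coordinate_fields(lines)
  if (!any(grepl("^ATOM  ", lines)))
    cp_stop(sprintf("no ATOM records in %s", path), "empty_structure_error")

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- suppressWarnings(bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  at$chain[is.na(at$chain)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1.0
  at$elesy[is.na(at$elesy)] <- ""

  at$element <- toupper(trimws(at$elesy))
  blank <- at$element == "" | at$element == "X"
  at$element[blank] <- infer_element(at$elety[blank], at$resid[blank],
                                     at$type[blank] == "HETATM")
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  at <- resolve_altlocs(at)

  is_water <- toupper(at$resid) %in% WATER_RESNAMES
  n_waters <- length(unique(residue_key(at$chain, at$resno, at$insert)[is_water]))
  at <- at[!is_water, , drop = FALSE]

  mk_atoms <- function(d) {
    out <- data.frame(
      serial = as.integer(d$eleno),
      name = trimws(d$elety),
      element = d$element,
      x = d$x, y = d$y, z = d$z,
      chain = d$chain,
      resno = as.integer(d$resno),
      insert = d$insert,
      resid = trimws(d$resid),
      occ = d$o,
      altloc = d$alt,
      is_hetero = d$type == "HETATM",
      stringsAsFactors = FALSE
    )
    out$res_key <- residue_key(out$chain, out$resno, out$insert)
    out
  }

  protein <- mk_atoms(at[at$type == "ATOM", , drop = FALSE])
  lig <- at[at$type == "HETATM", , drop = FALSE]
  lig <- lig[!(toupper(trimws(lig$resid)) %in% toupper(ligand_exclude)), ,
             drop = FALSE]
  ligands <- mk_atoms(lig)
  ligands$ligand_id <- if (nrow(ligands)) {
    paste(ligands$resid, ligands$chain, ligands$resno, sep = "_")
  } else character(0)

  protein <- withCallingHandlers(
    assign_radii(protein, radius_set = radius_set),
    conspocket_warning = function(w) invokeRestart("muffleWarning"))
  if (nrow(ligands))
    ligands <- withCallingHandlers(
      assign_radii(ligands, radius_set = radius_set),
      conspocket_warning = function(w) invokeRestart("muffleWarning"))

  structure(list(protein = protein, ligands = ligands,
                 n_waters_removed = n_waters,
                 source_id = source_id %||%
                   sub("\\.[^.]*$", "", basename(path))),
            class = "protein_complex")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.protein_complex <- function(x, ...) {
  cat(sprintf("<protein_complex> %s: %d protein atoms, %d ligand atoms (%d ligand group%s), %d water(s) removed\n",
              x$source_id, nrow(x$protein), nrow(x$ligands),
              length(unique(x$ligands$ligand_id)),
              if (length(unique(x$ligands$ligand_id)) == 1) "" else "s",
              x$n_waters_removed))
  invisible(x)
}

#' Write atoms back to a PDB file
#'
#' @param atoms An atom data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_atoms <- function(atoms, path) {
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   type = ifelse(atoms$is_hetero, "HETATM", "ATOM"),
                   eleno = atoms$serial, elety = atoms$name,
                   resid = atoms$resid, chain = atoms$chain,
                   resno = atoms$resno, insert = atoms$insert,
                   o = atoms$occ, b = rep(0, nrow(atoms)),
                   elesy = atoms$element)
  invisible(path)
}

#' Write pocket centres as PDB pseudo-atoms
#'
#' One HETATM record per pocket (residue name `PKT`, chain `P`), with the
#' pocket score in the B-factor column, so predictions can be inspected in
#' any molecular viewer alongside the structure.
#'
#' @param pockets A list of pockets (see [predict_pockets()]), ranked or not.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pocket_pdb <- function(pockets, path) {
  lines <- character(length(pockets))
  for (i in seq_along(pockets)) {
    p <- pockets[[i]]
    score <- if (is.null(p$score) || is.na(p$score)) 0 else p$score
    bcol <- sprintf("%6.1f", score)
    if (nchar(bcol) > 6) bcol <- sprintf("%6.0f", score)
    lines[i] <- sprintf("HETATM%5d  C   PKT P%4d    %8.3f%8.3f%8.3f%6.2f%s           C",
                        i, i, p$center[1], p$center[2], p$center[3], 1.0, bcol)
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
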