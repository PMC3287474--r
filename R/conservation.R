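# Step 2: residue conservation grades (ConSurf 1-9 colour scale) as a filter
# on cleft atoms. Grades are consumed precomputed; they are used ordinally
# (within-structure comparisons and sums only), never across families.

#' Parse a residue conservation grades file
#'
#' Two dialects are supported:
#' * `"consurf"`: the ConSurf-DB per-chain grades table. Rows carry a
#'   `RES<number>:<chain>` identifier (e.g. `SER42:A`) and an integer COLOR
#'   grade 1-9, possibly marked `8*` for insufficient data (the `*` is
#'   stripped).
#' * `"tsv"`: a plain 3-column table `chain <tab> residue_number <tab> grade`,
#'   with or without a header line.
#'
#' `"auto"` tries to detect the dialect from the content. Out-of-range grades
#' are clamped to \[1, 9\] with a warning.
#'
#' @param path Path to the grades file.
#' @param dialect `"auto"`, `"consurf"` or `"tsv"`.
#' @param chain_map Optional named character vector renaming chains, e.g.
#'   `c(E = "A")` maps the file's chain E to PDB chain A.
#' @return An object of class `conservation_map`: a named integer vector of
#'   grades keyed by `chain:residue_number:insertion_code`.
#' @export
parse_grades <- function(path, dialect = c("auto", "consurf", "tsv"),
                         chain_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    cp_stop(sprintf("grades file not found: %s", path), "input_error")
  lines <- readLines(path, warn = FALSE)

  consurf_pat <- "\\b([A-Z]{2,4})(-?[0-9]+):([A-Za-z0-9])\\b"
  if (dialect == "auto") {
    dialect <- if (any(grepl(consurf_pat, lines))) "consurf" else "tsv"
  }

  if (dialect == "consurf") {
    keep <- grepl(consurf_pat, lines)
    rows <- lines[keep]
    if (!length(rows))
      cp_stop(sprintf("no parseable ConSurf rows in %s", path), "format_error")
    m <- regmatches(rows, regexec(consurf_pat, rows))
    resno <- vapply(m, function(x) as.integer(x[3]), integer(1))
    chain <- vapply(m, function(x) x[4], character(1))
    # COLOR is the first integer token (optionally starred) after the
    # 3LATOM identifier and the real-valued SCORE column
    grade <- vapply(rows, function(r) {
      toks <- strsplit(trimws(r), "[ \t]+")[[1]]
      pos <- grep(consurf_pat, toks)[1]
      rest <- toks[-seq_len(pos)]
      col <- grep("^[0-9]\\*?$", rest, value = TRUE)
      if (!length(col)) return(NA_integer_)
      as.integer(sub("\\*$", "", col[1]))
    }, integer(1), USE.NAMES = FALSE)
    ok <- !is.na(grade)
    if (!any(ok))
      cp_stop(sprintf("no COLOR grades found in %s", path), "format_error")
    resno <- resno[ok]; chain <- chain[ok]; grade <- grade[ok]
  } else {
    rows <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
    parts <- strsplit(rows, "[ \t]+")
    ok <- vapply(parts, function(p)
      length(p) >= 3 && grepl("^-?[0-9]+$", p[2]) && grepl("^[0-9]+$", p[3]),
      logical(1))
    parts <- parts[ok]
    if (!length(parts))
      cp_stop(sprintf("no parseable rows in %s", path), "format_error")
    chain <- vapply(parts, `[`, character(1), 1)
    resno <- vapply(parts, function(p) as.integer(p[2]), integer(1))
    grade <- vapply(parts, function(p) as.integer(p[3]), integer(1))
  }

  if (!is.null(chain_map)) {
    hit <- chain %in% names(chain_map)
    chain[hit] <- unname(chain_map[chain[hit]])
  }
  if (any(grade < 1 | grade > 9)) {
    cp_warn(sprintf("%d grade(s) outside [1, 9] clamped", sum(grade < 1 | grade > 9)))
    grade <- pmin(pmax(grade, 1L), 9L)
  }
  key <- residue_key(chain, resno)
  dup <- duplicated(key)
  if (any(dup))
    cp_stop(sprintf("duplicate residue key(s) in %s: %s", path,
                    paste(unique(key[dup]), collapse = ", ")), "format_error")
  structure(stats::setNames(as.integer(grade), key), class = "conservation_map")
}

#' Conserved atom set (Set C)
#'
#' All heavy atoms belonging to residues whose conservation grade is greater
#' than or equal to `cutoff` (default 7 on the 1-9 scale). Residues absent
#' from the map are never retained; if more than 10% of the structure's
#' residues are unmapped a coverage warning is raised.
#'
#' @param atoms Atom data frame.
#' @param cmap A `conservation_map` from [parse_grades()].
#' @param cutoff Integer grade cutoff in \[1, 9\].
#' @return Integer vector of atom serials (sorted).
#' @export
conserved_atom_set <- function(atoms, cmap, cutoff = 7L) {
  if (is.na(cutoff) || cutoff < 1 || cutoff > 9)
    cp_stop("conservation cutoff must be in [1, 9]", "parameter_error")
  grades <- unname(cmap[atoms$res_key])
  res_keys <- unique(atoms$res_key)
  unmapped <- sum(!(res_keys %in% names(cmap)))
  if (unmapped > 0.10 * length(res_keys))
    cp_warn(sprintf("%d of %d residues (%.0f%%) have no conservation grade",
                    unmapped, length(res_keys),
                    100 * unmapped / length(res_keys)))
  grades[is.na(grades)] <- 0L
  sort(as.integer(atoms$serial[grades >= cutoff]))
}

#' Potential atom set (Set P)
#'
#' Conserved cleft atoms: the intersection of the cleft set with the
#' conserved set. These are the atoms clustered into candidate pockets.
#'
#' @param cleft Cleft atom serials.
#' @param set_c Conserved atom serials.
#' @return Integer vector of atom serials (sorted).
#' @export
potential_atoms <- function(cleft, set_c) {
  sort(intersect(as.integer(cleft), as.integer(set_c)))
}
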