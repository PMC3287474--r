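test_that("PDB splitting separates protein, ligands and waters", {
  p <- write_mini_pdb(c(
    pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_line("ATOM", 2, "CA", "GLY", "A", 2, 3, 0, 0),
    pdb_line("HETATM", 3, "O", "HOH", "A", 100, 9, 9, 9, elem = "O")
  ))
  cx <- read_pdb(p)
  expect_s3_class(cx, "protein_complex")
  expect_equal(nrow(cx$protein), 2)
  expect_equal(nrow(cx$ligands), 0)
  expect_equal(cx$n_waters_removed, 1)
})

test_that("altloc duplicates resolve to the highest-occupancy conformer", {
  p <- write_mini_pdb(c(
    pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, occ = 0.6, altloc = "A"),
    pdb_line("ATOM", 2, "CA", "GLY", "A", 1, 0.5, 0, 0, occ = 0.4, altloc = "B"),
    pdb_line("ATOM", 3, "CA", "GLY", "A", 2, 3, 0, 0)
  ))
  cx <- read_pdb(p)
  expect_equal(nrow(cx$protein), 2)
  kept <- cx$protein[cx$protein$resno == 1, ]
  expect_equal(kept$altloc, "A")
  expect_equal(kept$occ, 0.6)
})

test_that("distinct HETATM entities become distinct ligand groups", {
  p <- write_mini_pdb(c(
    pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_line("HETATM", 2, "MG", "MG", "A", 200, 5, 5, 5, elem = "MG"),
    pdb_line("HETATM", 3, "C1", "GOL", "A", 201, 8, 8, 8),
    pdb_line("HETATM", 4, "C2", "GOL", "A", 201, 9, 8, 8)
  ))
  cx <- read_pdb(p)
  expect_equal(length(unique(cx$ligands$ligand_id)), 2)
  expect_equal(sort(table(cx$ligands$ligand_id), decreasing = TRUE)[[1]], 2)
  # exclusion list removes an entity entirely
  cx2 <- read_pdb(p, ligand_exclude = "GOL")
  expect_equal(unique(cx2$ligands$ligand_id), "MG_A_200")
})

test_that("hydrogens are dropped and elements inferred from atom names", {
  p <- write_mini_pdb(c(
    pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0, elem = ""),
    pdb_line("ATOM", 2, "N", "GLY", "A", 1, 1.5, 0, 0, elem = ""),
    pdb_line("ATOM", 3, "HA", "GLY", "A", 1, 0.5, 1, 0, elem = "")
  ))
  cx <- read_pdb(p)
  expect_equal(nrow(cx$protein), 2)
  expect_setequal(cx$protein$element, c("C", "N"))
})

test_that("read errors carry useful context", {
  expect_error(read_pdb(tempfile()), class = "conspocket_input_error")
  only_het <- write_mini_pdb(pdb_line("HETATM", 1, "MG", "MG", "A", 1, 0, 0, 0,
                                      elem = "MG"))
  expect_error(read_pdb(only_het), class = "conspocket_empty_structure_error")
  bad <- write_mini_pdb(c(
    pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0),
    "ATOM      2  CA  GLY A   2      xx.xxx   0.000   0.000  1.00  0.00           C"
  ))
  expect_error(read_pdb(bad), "line 2", class = "conspocket_format_error")
})

test_that("van der Waals radii come from the chosen table", {
  at <- mk_atoms(rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0)))
  at$element <- c("C", "O", "X")
  expect_warning(out <- assign_radii(at), class = "conspocket_warning")
  expect_equal(out$radius, c(1.87, 1.40, 1.80))
  expect_equal(assign_radii(mk_atoms(cbind(0, 0, 0)), "bondi")$radius, 1.70)
  expect_error(assign_radii(at, "nonesuch"), class = "conspocket_config_error")
})

test_that("write/read round trip preserves serials, residues and coordinates", {
  fix <- make_pocketed_structure(fixture_spec(seed = 21))
  atoms <- rbind(fix$complex$protein,
                 fix$complex$ligands[, names(fix$complex$protein)])
  p <- tempfile(fileext = ".pdb")
  write_pdb_atoms(atoms, p)
  back <- read_pdb(p)
  expect_equal(back$protein$serial, fix$complex$protein$serial)
  expect_equal(back$protein$res_key, fix$complex$protein$res_key)
  expect_equal(back$protein$x, fix$complex$protein$x, tolerance = 1e-3)
  expect_equal(back$protein$z, fix$complex$protein$z, tolerance = 1e-3)
  # partition: every non-water heavy record lands in exactly one side
  expect_equal(nrow(back$protein) + nrow(back$ligands), nrow(atoms))
  expect_length(intersect(back$protein$serial, back$ligands$serial), 0)
})
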