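test_that("SASA matches closed forms for isolated and distant atoms", {
  one <- mk_atoms(cbind(0, 0, 0))
  s <- compute_sasa(one, probe = 1.4, n_points = 960)
  expect_equal(unname(s$area), 4 * pi * 3.27^2, tolerance = 1e-12)
  two_far <- mk_atoms(rbind(c(0, 0, 0), c(100, 0, 0)))
  s2 <- compute_sasa(two_far)
  expect_equal(unname(s2$area), rep(4 * pi * 3.27^2, 2), tolerance = 1e-12)
})

test_that("two close spheres match the spherical-cap closed form", {
  # equal expanded radii R, centres d apart: exposed area 2*pi*R*(R + d/2)
  d <- 2.0; R <- 1.87 + 1.4
  two <- mk_atoms(rbind(c(0, 0, 0), c(d, 0, 0)))
  s <- compute_sasa(two, n_points = 960)
  expect_equal(unname(s$area), rep(2 * pi * R * (R + d / 2), 2),
               tolerance = 0.02)
})

test_that("SASA is exactly translation invariant and stable under rotation", {
  at <- make_pocketed_structure(fixture_spec(seed = 2))$complex$protein
  at <- at[seq_len(150), ]
  s0 <- compute_sasa(at)
  shifted <- at
  shifted$x <- at$x + 13.7; shifted$y <- at$y - 4.2; shifted$z <- at$z + 0.9
  expect_identical(unname(compute_sasa(shifted)$area), unname(s0$area))
  rot <- withr::with_seed(5, random_rotation_matrix())
  rotated <- transform_atoms(at, rot, c(0, 0, 0))
  expect_equal(sum(compute_sasa(rotated)$area), sum(s0$area), tolerance = 0.01)
})

test_that("surface set uses a strict threshold", {
  fake <- structure(list(area = c(`1` = 1.5, `2` = 0.5, `3` = 1.0),
                         probe = 1.4, n_points = 960), class = "sasa_result")
  expect_equal(surface_set(fake, 1.0), 1L)
  expect_equal(surface_set(fake, 0), c(1L, 2L, 3L))
  expect_error(surface_set(fake, -1), class = "conspocket_parameter_error")
})

test_that("hull vertices are exactly the extreme points", {
  tetra <- mk_atoms(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  expect_equal(convex_hull_vertices(tetra), 1:4)
  cube <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  at <- mk_atoms(rbind(cube, c(0.5, 0.5, 0.5)))
  expect_equal(convex_hull_vertices(at), 1:8)
  expect_error(convex_hull_vertices(mk_atoms(rbind(c(0, 0, 0), c(1, 0, 0)))),
               class = "conspocket_geometry_error")
  copl <- mk_atoms(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)))
  expect_error(convex_hull_vertices(copl), class = "conspocket_geometry_error")
})

test_that("hull vertex set equals the LP membership oracle on random clouds", {
  skip_if_not_installed("boot")
  withr::with_seed(42, {
    for (rep in 1:3) {
      X <- matrix(stats::runif(3 * 80, 0, 30), ncol = 3)
      at <- mk_atoms(X)
      hv <- convex_hull_vertices(at)
      oracle <- which(vapply(seq_len(nrow(X)), function(i)
        !in_hull_lp(X[i, ], X[-i, , drop = FALSE]), logical(1)))
      expect_equal(hv, oracle)
    }
  })
})

test_that("hull expansion is inclusive and monotone in distance", {
  at <- mk_atoms(rbind(c(0, 0, 0), c(6.0, 0, 0), c(6.5, 0, 0), c(7.0, 0, 0)))
  q <- expand_hull(1L, at, 6.5)
  expect_true(all(c(1L, 2L, 3L) %in% q))   # 6.0 in, 6.5 exactly in
  expect_false(4L %in% q)                  # 7.0 out
  fix <- make_pocketed_structure(fixture_spec(seed = 4))
  atoms <- fix$complex$protein
  hull <- convex_hull_vertices(atoms)
  qs <- lapply(c(5.5, 6.5, 7.5), function(d) expand_hull(hull, atoms, d))
  expect_true(all(qs[[1]] %in% qs[[2]]))
  expect_true(all(qs[[2]] %in% qs[[3]]))
})

test_that("cleft is the exact set difference S minus Q", {
  expect_equal(cleft_atoms(c(1, 2, 3), c(2, 4)), c(1L, 3L))
  expect_length(cleft_atoms(c(1, 2), c(1, 2, 3)), 0)
  fix <- make_pocketed_structure(fixture_spec(seed = 4))
  sets <- atom_sets(fix$complex$protein, run_config())
  expect_setequal(sets$cleft, setdiff(sets$set_s, sets$set_q))
  expect_length(intersect(sets$cleft, sets$set_q), 0)
  expect_true(all(sets$cleft %in% sets$set_s))
  # cleft atoms lie inside the planted invagination
  cleft_xyz <- as.matrix(fix$complex$protein[
    fix$complex$protein$serial %in% sets$cleft, c("x", "y", "z")])
  proj <- cleft_xyz %*% c(1, 0, 0)
  perp <- sqrt(rowSums(cleft_xyz^2) - proj^2)
  expect_true(all(perp <= 7.0 + 3.6 + 0.5))
  expect_true(all(proj >= 18 - 10 - 3.6 - 0.5))
})
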