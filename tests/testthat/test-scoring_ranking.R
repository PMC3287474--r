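test_that("conservation score sums distinct residues once", {
  at <- mk_atoms(matrix(stats::runif(9), 3), resno = 1:3)
  pk <- merge_centers(list(1:3), at, 8)[[1]]
  expect_equal(conservation_score(pk, mk_cmap(c(7, 8, 9))), 24)
  # one residue contributing five atoms still counts once
  at5 <- mk_atoms(matrix(seq(0, 1.4, 0.1), 5), resno = rep(1, 5))
  pk5 <- merge_centers(list(1:5), at5, 8)[[1]]
  expect_equal(conservation_score(pk5, mk_cmap(7)), 7)
  expect_equal(conservation_score(pk5, mk_cmap(8, resno = 99)), 0)
  expect_equal(conservation_score(pk5, NULL), 0)
  expect_equal(conservation_score(pk5, mk_cmap(7), aggregate = "mean"), 7)
})

test_that("voxel volume matches sphere closed forms", {
  one <- mk_atoms(cbind(0.3, -0.2, 0.7))
  pk <- merge_centers(list(1L), one, 8)[[1]]
  v <- pocket_volume(pk, one, grid_step = 0.25)
  expect_equal(v, 4 / 3 * pi * 3.27^3, tolerance = 0.05)
  # disjoint spheres add
  two <- mk_atoms(rbind(c(0, 0, 0), c(50, 0, 0)))
  pk2 <- merge_centers(list(1:2), two, 60)[[1]]
  expect_equal(pocket_volume(pk2, two, 0.25), 2 * 4 / 3 * pi * 3.27^3,
               tolerance = 0.05)
  # overlapping spheres match the lens-subtraction closed form
  d <- 3.0; R <- 3.27
  lens <- pi * (4 * R + d) * (2 * R - d)^2 / 12
  ov <- mk_atoms(rbind(c(0, 0, 0), c(d, 0, 0)))
  pk3 <- merge_centers(list(1:2), ov, 8)[[1]]
  expect_equal(pocket_volume(pk3, ov, 0.25), 2 * 4 / 3 * pi * R^3 - lens,
               tolerance = 0.05)
  expect_error(pocket_volume(pk3, ov, 0), class = "conspocket_parameter_error")
  # translation consistency: global grid anchoring keeps the estimate stable
  shifted <- ov
  shifted$x <- ov$x + 17.13; shifted$y <- ov$y - 3.41
  pk4 <- merge_centers(list(1:2), shifted, 8)[[1]]
  expect_equal(pocket_volume(pk4, shifted, 0.25), pocket_volume(pk3, ov, 0.25),
               tolerance = 0.02)
})

test_that("volume is monotone under adding atoms", {
  at <- mk_atoms(rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0)))
  small <- merge_centers(list(1:2), at, 8)[[1]]
  big <- merge_centers(list(1:3), at, 8)[[1]]
  expect_gte(pocket_volume(big, at, 0.5), pocket_volume(small, at, 0.5))
})

test_that("ranking sorts by score with size then serial tie-breaks", {
  # three pockets: scores 24, 30, 24 with sizes 10, 5, 12
  xyz <- rbind(t(sapply(1:10, function(i) c(i * 2, 0, 0))),
               t(sapply(1:5, function(i) c(i * 2, 100, 0))),
               t(sapply(1:12, function(i) c(i * 2, 200, 0))))
  res <- c(1:10, 11:15, 16:27)
  at <- mk_atoms(xyz, resno = res)
  # residues 7-10 carry no grade and contribute 0
  cm <- mk_cmap(c(rep(4, 6), rep(6, 5), rep(2, 12)),
                resno = c(1:6, 11:27))
  pks <- merge_centers(list(1:10, 11:15, 16:27), at, 8)
  # scores: p1 = 6*4=24, p2 = 5*6=30, p3 = 12*2=24
  rp <- rank_pockets(pks, "conservation", cmap = cm, structure_id = "ties")
  expect_equal(vapply(rp$pockets, function(p) p$score, numeric(1)), c(30, 24, 24))
  expect_equal(length(rp$pockets[[2]]$member_atoms), 12) # bigger 24 first
  expect_equal(length(rp$pockets[[3]]$member_atoms), 10)
  expect_equal(vapply(rp$pockets, function(p) p$rank, integer(1)), 1:3)
  # single pocket gets rank 1; ranking is a permutation
  one <- rank_pockets(pks[1], "conservation", cmap = cm)
  expect_equal(one$pockets[[1]]$rank, 1L)
  expect_setequal(unlist(lapply(rp$pockets, function(p) p$member_atoms)),
                  unlist(lapply(pks, function(p) p$member_atoms)))
})

test_that("conservation and volume ranking disagree on a contrast fixture", {
  # a small, deeply conserved pocket vs a large variable cleft
  xyz <- rbind(t(sapply(1:4, function(i) c(i * 2.5, 0, 0))),
               t(sapply(1:20, function(i) c(i * 2.5, 80, 0))))
  at <- mk_atoms(xyz, resno = 1:24)
  cm <- mk_cmap(c(rep(9, 4), rep(1, 20)), resno = 1:24)
  pks <- merge_centers(list(1:4, 5:24), at, 8)
  by_cons <- rank_pockets(pks, "conservation", cmap = cm, atoms = at)
  by_vol <- rank_pockets(pks, "volume", atoms = at)
  expect_equal(length(by_cons$pockets[[1]]$member_atoms), 4)
  expect_equal(length(by_vol$pockets[[1]]$member_atoms), 20)
})
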