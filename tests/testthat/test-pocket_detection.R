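test_that("single-linkage clustering joins chains and respects the cut", {
  at <- mk_atoms(rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_length(cluster_atoms(at, at$serial, 4.5, min_pocket_atoms = 1), 1)
  chain <- mk_atoms(rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0)))
  cl <- cluster_atoms(chain, chain$serial, 4.5, min_pocket_atoms = 1)
  expect_length(cl, 1)            # transitivity: ends 6 apart still join
  expect_equal(cl[[1]], 1:3)
  far <- mk_atoms(rbind(c(0, 0, 0), c(3, 0, 0), c(20, 0, 0)))
  expect_length(cluster_atoms(far, far$serial, 4.5, min_pocket_atoms = 1), 2)
  # empty input is a no-pocket outcome, not an error
  expect_equal(cluster_atoms(at, integer(0), 4.5), list())
  # small clusters are discarded
  expect_length(cluster_atoms(far, far$serial, 4.5, min_pocket_atoms = 3), 0)
})

test_that("threshold-cut partition equals a brute-force union-find", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      X <- matrix(stats::runif(3 * 60, 0, 25), ncol = 3)
      at <- mk_atoms(X)
      for (d in c(2, 4, 8)) {
        got <- cluster_atoms(at, at$serial, d, min_pocket_atoms = 1)
        want <- uf_components(X, d)
        expect_equal(canonical_partition(got), canonical_partition(want))
      }
    }
  })
})

test_that("centre merging unions clusters and recomputes centres to a fixpoint", {
  # two 2-atom clusters, centres 5 apart -> one pocket with recomputed centre
  at <- mk_atoms(rbind(c(-1, 0, 0), c(1, 0, 0), c(4, 0, 0), c(6, 0, 0)))
  pk <- merge_centers(list(c(1L, 2L), c(3L, 4L)), at, merge_dist = 8)
  expect_length(pk, 1)
  expect_equal(unname(pk[[1]]$center), c(2.5, 0, 0))
  expect_equal(pk[[1]]$member_atoms, 1:4)
  # centres 9 apart stay separate
  at2 <- mk_atoms(rbind(c(0, 0, 0), c(0, 1, 0), c(9, 0, 0), c(9, 1, 0)))
  expect_length(merge_centers(list(c(1L, 2L), c(3L, 4L)), at2, 8), 2)
  # chaining: centres at 0, 7, 14 collapse through iteration
  at3 <- mk_atoms(rbind(c(0, 0, 0), c(7, 0, 0), c(14, 0, 0)))
  pk3 <- merge_centers(list(1L, 2L, 3L), at3, 8)
  expect_length(pk3, 1)
  expect_equal(unname(pk3[[1]]$center), c(7, 0, 0))
  # fixpoint guarantee on random instances
  withr::with_seed(11, {
    X <- matrix(stats::runif(3 * 40, 0, 40), ncol = 3)
    at4 <- mk_atoms(X)
    pk4 <- merge_centers(as.list(seq_len(40)), at4, 8)
    if (length(pk4) > 1) {
      centers <- t(vapply(pk4, function(p) p$center, numeric(3)))
      expect_gt(min(dist(centers)), 8)
    }
  })
})

test_that("pockets partition the potential set with deterministic ordering", {
  fix <- make_pocketed_structure(fixture_spec(seed = 9))
  pk <- predict_pockets(fix$complex, fix$cmap)
  members <- unlist(lapply(pk, function(p) p$member_atoms))
  expect_equal(anyDuplicated(members), 0)
  sizes <- vapply(pk, function(p) length(p$member_atoms), integer(1))
  expect_true(all(diff(sizes) <= 0))
  pk2 <- predict_pockets(fix$complex, fix$cmap)
  expect_identical(pk, pk2)     # bit-identical rerun
})

test_that("the full pipeline recovers planted pockets and respects the filter", {
  fix <- make_pocketed_structure(fixture_spec(seed = 10))
  pk <- predict_pockets(fix$complex, fix$cmap)
  expect_gte(length(pk), 1)
  d <- sqrt(sum((pk[[1]]$center - fix$ground_truth[[1]])^2))
  expect_lte(d, 4)
  # all grades variable -> conservation filter removes everything
  flat <- fix$cmap
  flat[] <- 1L
  expect_length(predict_pockets(fix$complex, flat), 0)
  # two pockets planted far apart -> exactly two pockets
  spec2 <- fixture_spec(shell_radius = 20,
                        pockets = list(
                          list(direction = c(1, 0, 0), mouth_radius = 7, depth = 10),
                          list(direction = c(-1, 0, 0), mouth_radius = 7, depth = 10)),
                        seed = 12)
  fix2 <- make_pocketed_structure(spec2)
  expect_gt(sqrt(sum((fix2$ground_truth[[1]] - fix2$ground_truth[[2]])^2)), 20)
  pk2 <- predict_pockets(fix2$complex, fix2$cmap)
  expect_length(pk2, 2)
})

test_that("pocket prediction is equivariant under rigid motion", {
  fix <- make_pocketed_structure(fixture_spec(seed = 13))
  cfg <- run_config()
  pk <- predict_pockets(fix$complex, fix$cmap, cfg)
  rot <- withr::with_seed(14, random_rotation_matrix())
  shift <- c(11.3, -7.2, 23.9)
  moved <- fix$complex
  moved$protein <- transform_atoms(moved$protein, rot, shift)
  moved$ligands <- transform_atoms(moved$ligands, rot, shift)
  pk_m <- predict_pockets(moved, fix$cmap, cfg)
  expect_equal(length(pk_m), length(pk))
  for (i in seq_along(pk)) {
    expect_identical(pk_m[[i]]$member_atoms, pk[[i]]$member_atoms)
    expect_equal(unname(pk_m[[i]]$center),
                 unname(as.numeric(rot %*% pk[[i]]$center + shift)),
                 tolerance = 1e-6)
  }
})
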