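test_that("streamline length is the sum of segment lengths", {
  pts <- cbind(0, 0, 0:10)
  expect_equal(streamline_length(pts), 10)
  expect_equal(streamline_length(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  expect_equal(streamline_length(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))), 2)
  expect_error(streamline_length(rbind(c(0, 0, 0))), "2 points")
})

test_that("straight-bundle tracking connects the two truth regions only", {
  tp <- straight_bundle_phantom()
  sl <- fact_track(tp$tf)
  expect_gt(length(sl), 50)
  # every retained streamline obeys the FA threshold and the length window
  prm <- tracking_params()
  for (s in sl[seq(1, length(sl), by = 17)]) {
    expect_true(all(s$fa >= prm$fa_threshold))
    expect_true(s$length >= prm$min_length_mm && s$length <= prm$max_length_mm)
    expect_lt(max(sqrt(rowSums(diff(s$points)^2))), prm$step_mm + 1e-9)
  }
  cn <- build_connectome(sl, tp$parcellation, tp$tf)
  expect_gte(cn$fiber_number[1, 2] / length(sl), 0.95)
  off <- cn$fiber_number; off[1, 2] <- off[2, 1] <- 0
  expect_true(all(off == 0))
  expect_true(all(cn$mean_fa[cn$fiber_number > 0] > 0.2))
  expect_true(all(cn$mean_length[cn$fiber_number > 0] > 0))
})

test_that("tracking stops in a zero-FA field and at sharp bends", {
  flat <- straight_bundle_phantom()$tf
  flat$fa[] <- 0
  expect_warning(sl0 <- fact_track(flat), "empty seed mask")
  expect_length(sl0, 0)

  kink <- rbind(cbind(5, 5, seq(2, 18)), cbind(5, seq(6, 18), 18))
  tk <- generate_tract_phantom(2, list(list(regions = c(1, 2), points = kink)))
  slk <- fact_track(tk$tf)
  expect_gt(length(slk), 0)
  cnk <- build_connectome(slk, tk$parcellation, tk$tf)
  expect_equal(cnk$fiber_number[1, 2], 0)

  # at a 91-degree threshold the same geometry is traversable
  sl_open <- fact_track(tk$tf, tracking_params(angle_threshold_deg = 90))
  cn_open <- build_connectome(sl_open, tk$parcellation, tk$tf)
  expect_gt(cn_open$fiber_number[1, 2], 0)
})

test_that("two disjoint bundles give exactly two connectome edges", {
  tp <- generate_tract_phantom(4, list(
    list(regions = c(1, 2), points = cbind(5, 10, seq(2, 37))),
    list(regions = c(3, 4), points = cbind(14, 10, seq(2, 37)))))
  expect_equal(nrow(tp$truth_adjacency), 2)
  sl <- fact_track(tp$tf)
  cn <- build_connectome(sl, tp$parcellation, tp$tf)
  ut <- cn$fiber_number[upper.tri(cn$fiber_number)]
  expect_equal(sum(ut > 0), 2)
  expect_gt(cn$fiber_number[1, 2], 0)
  expect_gt(cn$fiber_number[3, 4], 0)
  expect_error(generate_tract_phantom(2, list(list(regions = c(1, 2),
                                                   points = cbind(5, 10, seq(2, 50))))),
               "exits the grid")
})

test_that("connectome respects relabeling and unlabeled endpoints", {
  tp <- straight_bundle_phantom()
  sl <- fact_track(tp$tf)
  cn <- build_connectome(sl, tp$parcellation, tp$tf)
  # permute labels 1<->2: matrices conjugate by the permutation
  parc2 <- tp$parcellation
  parc2[tp$parcellation == 1] <- 2L
  parc2[tp$parcellation == 2] <- 1L
  cn2 <- build_connectome(sl, parc2, tp$tf)
  P <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(cn2$fiber_number, P %*% cn$fiber_number %*% t(P))
  expect_equal(cn2$mean_length, P %*% cn$mean_length %*% t(P))

  # unlabeled endpoints contribute to no pair
  parc0 <- tp$parcellation
  parc0[tp$parcellation == 2] <- 0L
  cn0 <- build_connectome(sl, parc0, tp$tf, n_regions = 2)
  expect_true(all(cn0$fiber_number == 0))

  expect_error(build_connectome(sl, array(0L, c(2, 2, 2)), tp$tf), "grid")
})

test_that("seeding density scales streamline counts, not topology", {
  tp <- straight_bundle_phantom()
  sl1 <- fact_track(tp$tf)
  sl2 <- fact_track(tp$tf, tracking_params(seeds_per_voxel = 2L, seed = 4))
  expect_lt(abs(length(sl2) / length(sl1) - 2), 0.1 * 2)
  cn1 <- build_connectome(sl1, tp$parcellation, tp$tf)
  cn2 <- build_connectome(sl2, tp$parcellation, tp$tf)
  expect_identical(cn1$fiber_number > 0, cn2$fiber_number > 0)
})

test_that("connectome TSV round-trips", {
  tp <- straight_bundle_phantom()
  cn <- build_connectome(fact_track(tp$tf), tp$parcellation, tp$tf)
  dir <- withr::local_tempdir()
  write_connectome(cn, dir)
  back <- read_connectome(dir)
  expect_equal(back$fiber_number, cn$fiber_number)
  expect_equal(back$mean_length, cn$mean_length, tolerance = 1e-9)
})
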