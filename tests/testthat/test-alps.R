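test_that("spherical ROI rasterization matches exhaustive enumeration", {
  gs <- c(11L, 11L, 11L)
  vox <- rasterize_roi(c(5, 5, 5), 5, c(2, 2, 2), gs)
  # independent enumeration of the 3x3x3 neighbourhood
  nb <- as.matrix(expand.grid(4:6, 4:6, 4:6))
  dmm <- sqrt(rowSums((2 * sweep(nb, 2, c(5, 5, 5)))^2))
  expected <- nb[dmm <= 2.5, , drop = FALSE]
  expect_equal(nrow(vox), 7)
  expect_setequal(apply(unname(vox), 1, paste, collapse = ","),
                  apply(unname(expected), 1, paste, collapse = ","))

  one <- rasterize_roi(c(5, 5, 5), 2, c(2, 2, 2), gs)
  expect_equal(nrow(one), 1)

  expect_warning(clip <- rasterize_roi(c(0, 0, 0), 5, c(2, 2, 2), gs), "clipped")
  expect_true(attr(clip, "clipped"))
  expect_lt(nrow(clip), 7)
})

test_that("ROI placement validates inputs and flags low-FA placements", {
  ph <- generate_dwi_phantom(small_phantom_config())
  tf <- fit_tensor(ph$dwi)
  rois <- place_default_rois(ph$truth, tf = tf)
  expect_length(rois$qc_flags, 0)
  expect_named(rois$rois, c("proj_L", "proj_R", "assoc_L", "assoc_R"))

  expect_error(place_default_rois(list(proj_L = c(1, 1, 1), proj_R = c(2, 2, 2),
                                       assoc_L = c(3, 3, 3))), "missing ROI centers")

  # a center in the isotropic ventricle has FA ~ 0 -> flag
  bad <- place_default_rois(list(proj_L = c(11, 11, 5), proj_R = c(16, 11, 5),
                                 assoc_L = c(3, 11, 5), assoc_R = c(20, 11, 5)),
                            tf = tf)
  expect_true(any(grepl("proj_L", bad$qc_flags)))
})

test_that("ALPS pipeline reproduces the analytic oracle on noiseless phantoms", {
  ph <- generate_dwi_phantom(small_phantom_config())
  tf <- fit_tensor(ph$dwi)
  res <- compute_alps(tf, place_default_rois(ph$truth))
  expect_equal(res$mean_alps, as.numeric(analytic_alps(ph$truth)), tolerance = 1e-6)
  expect_equal(res$mean_alps, 1.8, tolerance = 1e-6)
  expect_equal(res$mean_alps, (res$alps_L + res$alps_R) / 2)
  expect_true(all(res$roi_voxel_counts >= 1))
})

test_that("hemisphere asymmetry resolves per side and averages bilaterally", {
  cfg <- small_phantom_config(perivascular_delta = c(L = 0.24, R = 0.285))
  ph <- generate_dwi_phantom(cfg)
  tf <- fit_tensor(ph$dwi)
  res <- compute_alps(tf, place_default_rois(ph$truth))
  expect_equal(res$alps_L, 1.8, tolerance = 1e-6)
  expect_equal(res$alps_R, 1.95, tolerance = 1e-6)
  expect_equal(res$mean_alps, 1.875, tolerance = 1e-6)

  # swapping the left/right ROI labels swaps the per-side indices only
  rois <- place_default_rois(ph$truth)
  swapped <- rois
  swapped$rois <- rois$rois[c("proj_R", "proj_L", "assoc_R", "assoc_L")]
  names(swapped$rois) <- c("proj_L", "proj_R", "assoc_L", "assoc_R")
  res2 <- compute_alps(tf, swapped)
  expect_equal(res2$alps_L, res$alps_R)
  expect_equal(res2$alps_R, res$alps_L)
  expect_equal(res2$mean_alps, res$mean_alps)
})

test_that("ALPS is invariant to global diffusivity rescaling", {
  ph <- generate_dwi_phantom(small_phantom_config())
  tf <- fit_tensor(ph$dwi)
  res <- compute_alps(tf, place_default_rois(ph$truth))
  tf2 <- tf
  for (nm in c("dxx", "dyy", "dzz")) tf2[[nm]] <- 3.7 * tf2[[nm]]
  res2 <- compute_alps(tf2, place_default_rois(ph$truth))
  expect_equal(res2$mean_alps, res$mean_alps, tolerance = 1e-12)
})

test_that("Rician noise at snr 30 leaves the mean ALPS within 2% of noiseless", {
  noiseless <- {
    ph <- generate_dwi_phantom(small_phantom_config())
    compute_alps(fit_tensor(ph$dwi), place_default_rois(ph$truth))$mean_alps
  }
  vals <- vapply(1:50, function(s) {
    ph <- generate_dwi_phantom(small_phantom_config(snr = 30, seed = 100 + s))
    compute_alps(fit_tensor(ph$dwi), place_default_rois(ph$truth))$mean_alps
  }, numeric(1))
  expect_lt(abs(mean(vals) - noiseless) / noiseless, 0.02)
})

test_that("batch ALPS handles multiple subjects, duplicates, and failures", {
  mk <- function(delta, seed) {
    ph <- generate_dwi_phantom(small_phantom_config(perivascular_delta = delta, seed = seed))
    list(dwi = ph$dwi, truth = ph$truth)
  }
  subs <- list(s1 = mk(0, 1), s2 = mk(0.24, 2), s3 = mk(0.285, 3))
  tab <- alps_batch(subs)
  expect_equal(tab$mean_alps, c(1.0, 1.8, 1.95), tolerance = 1e-3)

  expect_error(alps_batch(list()), "empty")
  dup <- subs; names(dup) <- c("s1", "s1", "s3")
  expect_error(alps_batch(dup), "unique")

  subs$s2 <- list(dwi_dir = file.path(tempdir(), "no-such-dir"))
  tab2 <- alps_batch(subs)
  expect_equal(sum(is.na(tab2$mean_alps)), 1)
  expect_true(!is.na(tab2$error[tab2$id == "s2"]))
})
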