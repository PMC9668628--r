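# synthetic FA map of a filled (possibly rotated) ellipse on a grid
blob_map <- function(n = 64, h = 0.78125, a = 8, b = 4, rot_deg = 0,
                     value = 0.6) {
  ctr <- n * h / 2
  x <- outer(rep(1, n), (seq_len(n) - 0.5) * h - ctr)   # left
  y <- -outer((seq_len(n) - 0.5) * h - ctr, rep(1, n))  # anterior
  rho <- rot_deg * pi / 180
  u <- cos(rho) * x + sin(rho) * y
  v <- -sin(rho) * x + cos(rho) * y
  value * ((u / a)^2 + (v / b)^2 <= 1)
}

test_that("the initial ellipse matches the cord's moments", {
  run <- noiseless_run()
  tm <- fit_tensor_map(crop_to_intraspinal(run$dwi, "auto"))
  fa <- tm$scalar_maps$FA; fa[is.na(fa)] <- 0
  e0 <- init_ellipse(fa, tm$spacing_mm)
  bb <- attr(crop_to_intraspinal(run$dwi, "auto"), "bbox")
  true_ctr <- c(50 - bb[1] * 0.78125, 50 - bb[3] * 0.78125)
  expect_lt(max(abs(e0$center_mm - true_ctr)), 0.78125)
  expect_equal(e0$semi_axes_mm, 0.63 * c(6.5, 4), tolerance = 0.12)

  # a disc gives equal axes
  ed <- init_ellipse(blob_map(a = 6, b = 6), 0.78125)
  expect_equal(ed$semi_axes_mm[1], ed$semi_axes_mm[2], tolerance = 0.03)

  # rotating the input rotates the recovered ellipse
  er0 <- init_ellipse(blob_map(rot_deg = 0), 0.78125)
  er10 <- init_ellipse(blob_map(rot_deg = 10), 0.78125)
  expect_equal(er10$rotation_deg - er0$rotation_deg, 10, tolerance = 1)

  expect_error(init_ellipse(matrix(0, 16, 16), 1), "empty cord mask")
})

test_that("profile sampling follows the 600-point convention", {
  prof <- noiseless_run()$res$profile
  expect_length(prof$values, 600L)
  expect_equal(prof$sampling_step_deg, 0.6)

  cst <- matrix(0.5, 40, 40)
  e <- cord_ellipse(c(15, 15), c(6, 4))
  pc <- sample_profile(cst, 0.78125, e)
  expect_equal(max(abs(pc$values - 0.5)), 0, tolerance = 1e-12)

  # left-right symmetric phantom: profile(theta) = profile(360 - theta)
  v <- prof$values
  mir <- c(v[1], rev(v[-1]))
  expect_equal(v, mir, tolerance = 1e-3)

  huge <- cord_ellipse(c(15, 15), c(60, 40))
  expect_error(sample_profile(cst, 0.78125, huge), "exits")
})

test_that("ellipse refinement ascends and reaches a fixed point", {
  run <- noiseless_run()
  cr <- crop_to_intraspinal(run$dwi, "auto")
  tm <- fit_tensor_map(cr)
  fa <- tm$scalar_maps$FA; fa[is.na(fa)] <- 0
  e0 <- init_ellipse(fa, tm$spacing_mm)
  obj0 <- cordDTI:::profile_contrast(sample_profile(fa, tm$spacing_mm, e0))
  e1 <- refine_ellipse(fa, tm$spacing_mm, e0)
  expect_gte(attr(e1, "objective"), obj0)
  e2 <- refine_ellipse(fa, tm$spacing_mm, e1)
  expect_lt(abs(attr(e2, "objective") - attr(e1, "objective")),
            1e-4 * abs(attr(e1, "objective")) + 1e-12)
})

test_that("landmarks locate the midline, transversal line and horns", {
  run <- noiseless_run()
  ell <- run$res$ellipse
  truth_ang <- run$truth$landmark_angles_deg
  dmid <- abs(((ell$midline_angle_deg - truth_ang$midline + 180) %% 360) - 180)
  expect_lt(dmid, 1)
  expect_equal(ell$transversal_angle_deg, truth_ang$transversal,
               tolerance = 2 / 90)
  expect_equal(unname(ell$posterior_horn_angles_deg),
               unname(truth_ang$posterior_horns), tolerance = 3 / 145)

  # no gray matter: flat profile must raise a landmark failure
  cst <- matrix(0.5, 40, 40)
  e <- cord_ellipse(c(15, 15), c(6, 4))
  pc <- sample_profile(cst, 0.78125, e)
  expect_error(detect_landmarks(pc, e), "landmark failure")
})

test_that("landmark detection is invariant to intensity scaling", {
  run <- noiseless_run()
  cr <- crop_to_intraspinal(run$dwi, "auto")
  tm <- fit_tensor_map(cr)
  fa <- tm$scalar_maps$FA; fa[is.na(fa)] <- 0
  e1 <- refine_ellipse(fa, tm$spacing_mm, init_ellipse(fa, tm$spacing_mm))
  l1 <- detect_landmarks(sample_profile(fa, tm$spacing_mm, e1), e1)
  sc <- fa * 0.5
  l2 <- detect_landmarks(sample_profile(sc, tm$spacing_mm, e1), e1,
                         min_depth = 0.025)
  expect_equal(l1$posterior_horn_angles_deg, l2$posterior_horn_angles_deg,
               tolerance = 1e-6)
  expect_equal(l1$midline_angle_deg, l2$midline_angle_deg)
})

test_that("ROI placement puts 21 fine-grid pixels in mirrored positions", {
  res <- noiseless_run()$res
  rois <- res$rois
  expect_identical(sort(unique(rois$n_px)), 21L)
  # left/right centres mirror
  for (rg in c("PT", "DC", "AH")) {
    l <- rois[rois$region == rg & rois$side == "L", ]
    r <- rois[rois$region == rg & rois$side == "R", ]
    expect_equal(l$center_row_mm, r$center_row_mm, tolerance = 0.78125)
    mid_col <- mean(rois$center_col_mm[rois$region == "DC"])
    expect_equal(l$center_col_mm - mid_col, mid_col - r$center_col_mm,
                 tolerance = 0.78125)
  }
  # PT centre angle lies strictly between horn and transversal angles
  ell <- res$ellipse
  pt_l <- rois$angle_deg[rois$region == "PT" & rois$side == "L"]
  expect_true(pt_l > ell$transversal_angle_deg &
              pt_l < ell$posterior_horn_angles_deg[["left"]])

  bare <- cord_ellipse(c(10, 10), c(4, 3))
  expect_error(place_rois(bare, c(100, 100)), "landmarks")
})

test_that("ROI means average the member pixels", {
  res <- noiseless_run()$res
  rois <- res$rois
  cst <- matrix(0.5, 1000, 1000)
  st <- roi_stats(list(FA = cst), rois)
  expect_equal(st$mean, rep(0.5, nrow(st)))
  # bilateral rows are exactly (L + R) / 2
  full <- roi_stats(list(FA = cst + runif(length(cst)) * 0), rois)
  for (rg in c("PT", "DC", "AH")) {
    lr <- full$mean[full$region == rg & full$side %in% c("L", "R")]
    bi <- full$mean[full$region == rg & full$side == "bilateral"]
    expect_identical(bi, mean(lr))
  }
})

test_that("PT-region values are recovered through the ROI chain", {
  run <- noiseless_run()
  asg <- default_tissue_tensors()
  expect_equal(bilateral_roi_mean(run$res$roi_means, "PT", "FA"),
               truth_region_value(asg, "lateral_column_PT", "FA"),
               tolerance = 0.01 / 0.67)
  expect_equal(bilateral_roi_mean(run$res$roi_means, "PT", "RD"),
               truth_region_value(asg, "lateral_column_PT", "RD"),
               tolerance = 0.01 / 0.16)
})

test_that("noisy phantoms keep ROI means close to tissue truth", {
  asg <- default_tissue_tensors()
  fa_ok <- c(); rd_ok <- c()
  for (s in 1:50) {
    spec <- phantom_spec(snr = 20, seed = 200 + s)
    res <- suppressWarnings(run_subject(simulate_dwi(make_cord_geometry(spec)),
                                        "p"))
    expect_false(is.null(res$roi_means))
    for (rg in names(region_label)) {
      fa_ok <- c(fa_ok, abs(bilateral_roi_mean(res$roi_means, rg, "FA") -
                   truth_region_value(asg, region_label[[rg]], "FA")) < 0.05)
      rd_ok <- c(rd_ok, abs(bilateral_roi_mean(res$roi_means, rg, "RD") -
                   truth_region_value(asg, region_label[[rg]], "RD")) < 0.03)
    }
  }
  expect_gte(mean(fa_ok), 0.9)
  expect_gte(mean(rd_ok), 0.9)
})
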