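test_that("cropping conventions and auto-detection behave", {
  spec <- small_spec()
  truth <- make_cord_geometry(spec)
  dwi <- simulate_dwi(truth)
  n <- dim(dwi$volumes)[1]

  # whole-grid box is the identity
  whole <- crop_to_intraspinal(dwi, c(0L, n, 0L, n))
  expect_equal(whole$volumes, dwi$volumes)

  # half-open convention
  ten <- crop_to_intraspinal(dwi, c(0L, 10L, 0L, 10L))
  expect_equal(dim(ten$volumes)[1:2], c(10L, 10L))
  expect_equal(ten$volumes[, , 1], dwi$volumes[1:10, 1:10, 1])

  # auto box contains the full cord
  auto <- crop_to_intraspinal(dwi, "auto")
  bb <- attr(auto, "bbox")
  cord_mask_true <- matrix(!(truth$label_map %in% c("background", "csf")),
                           nrow(truth$label_map))
  cord <- which(cord_mask_true, arr.ind = TRUE)
  expect_true(min(cord[, 1]) > bb[1] & max(cord[, 1]) <= bb[2])
  expect_true(min(cord[, 2]) > bb[3] & max(cord[, 2]) <= bb[4])

  expect_error(crop_to_intraspinal(dwi, c(0L, 0L, 0L, 10L)), "empty")
  expect_error(crop_to_intraspinal(dwi, c(-1L, 10L, 0L, 10L)), "outside")
})

test_that("midsagittal profiles average a symmetric centred band", {
  u <- matrix(3, 20, 16)
  expect_equal(midsagittal_profile(u), rep(3, 20))
  img <- matrix(0, 20, 16); img[7, ] <- 5
  expect_equal(which.max(midsagittal_profile(img)), 7L)
  expect_error(midsagittal_profile(u, band_width_px = 17), "wider")
  # symmetric image: band centred on the midline equals its mirror
  spec <- small_spec()
  b0 <- simulate_dwi(make_cord_geometry(spec))$volumes[, , 1]
  expect_equal(midsagittal_profile(b0),
               midsagittal_profile(b0[, ncol(b0):1]))
})

test_that("shift estimation is exact, sub-pixel and antisymmetric", {
  spec <- small_spec()
  b0 <- simulate_dwi(make_cord_geometry(spec))$volumes[, , 1]
  p <- midsagittal_profile(b0)
  expect_equal(as.numeric(estimate_ap_shift(p, p)), 0)

  # integer circular shift
  p3 <- c(utils::tail(p, 3), utils::head(p, -3))
  expect_equal(as.numeric(estimate_ap_shift(p3, p)), 3, tolerance = 0.05 / 3)

  # sub-pixel shift of the underlying image (same-contrast profiles)
  p15 <- midsagittal_profile(shift_rows(b0, 1.5))
  expect_lt(abs(as.numeric(estimate_ap_shift(p15, p)) - 1.5), 0.25)

  expect_error(estimate_ap_shift(rep(1, 40), rep(1, 40)), "flat")

  # antisymmetry over constructed shifts
  for (d in c(-4, -2, 1, 3)) {
    pd <- midsagittal_profile(shift_rows(b0, d))
    f <- as.numeric(estimate_ap_shift(pd, p))
    b <- as.numeric(estimate_ap_shift(p, pd))
    expect_equal(f, -b, tolerance = 0.1, ignore_attr = TRUE)
  }
})

test_that("motion correction recovers injected shifts and is stable", {
  shifts <- c(0, 2, -1, 0, 1, -2, 3)
  spec <- phantom_spec(shift_per_volume_px = shifts)
  dwi <- simulate_dwi(make_cord_geometry(spec))
  cr <- crop_to_intraspinal(dwi, "auto")
  mc <- motion_correct(cr)

  expect_equal(mc$shifts$shift_px, shifts, tolerance = 0.25,
               ignore_attr = TRUE)
  expect_false(any(mc$shifts$at_bound))
  # structure is preserved and the b0 is untouched
  expect_identical(dim(mc$dwi$volumes), dim(cr$volumes))
  expect_identical(mc$dwi$volumes[, , 1], cr$volumes[, , 1])
  expect_equal(mc$shifts$shift_px[mc$shifts$is_b0], 0)

  # a shift-free stack is (nearly) a fixed point
  spec0 <- phantom_spec()
  cr0 <- crop_to_intraspinal(simulate_dwi(make_cord_geometry(spec0)), "auto")
  mc0 <- motion_correct(cr0)
  expect_lt(max(abs(mc0$shifts$shift_px)), 0.1)
  expect_equal(mc0$dwi$volumes, cr0$volumes, tolerance = 0.02)

  # correcting the corrected stack leaves residuals below 0.1 px
  mc2 <- motion_correct(mc$dwi)
  expect_lt(max(abs(mc2$shifts$shift_px)), 0.1)
})

test_that("spectral row translation is exact for circular shifts", {
  m <- matrix(rnorm(32 * 5), 32, 5)
  s3 <- shift_rows(m, 3)
  expect_equal(s3, m[c(30:32, 1:29), ], tolerance = 1e-10)
  # forward then backward restores band-limited input (the real-valued
  # Nyquist projection makes fractional shifts lossy only at Nyquist)
  k <- (1:32) / 32
  smooth <- outer(sin(2 * pi * k) + 0.5 * cos(4 * pi * k), c(1, 2, -1))
  expect_equal(shift_rows(shift_rows(smooth, 1.3), -1.3), smooth,
               tolerance = 1e-10)
})
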