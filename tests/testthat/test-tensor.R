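test_that("the log-linear design matrix is well posed", {
  sc <- default_scheme()
  X <- build_design(sc)
  expect_equal(dim(X), c(7L, 7L))
  # independent rank check via singular values
  sv <- svd(X)$d
  expect_gt(min(sv) / max(sv), 1e-6)
  # b0 row: no diffusion weighting, intercept 1
  expect_equal(X[1, ], c(rep(0, 6), 1))
  # duplicated direction degenerates the scheme
  dirs <- sc$directions; dirs[7, ] <- dirs[6, ]
  expect_error(build_design(gradient_scheme(dirs, sc$b_values)),
               "rank")
})

test_that("noiseless tensors are recovered exactly", {
  spec <- small_spec()
  truth <- make_cord_geometry(spec)
  # hard-edged rasterisation: every labelled pixel is pure tissue, so
  # the exactly determined 7-volume solve must return the assignment
  dwi <- simulate_dwi(truth, supersample = 1L)
  tm <- fit_tensor_map(dwi)
  asg <- default_tissue_tensors()
  for (lab in c("lateral_column_PT", "dorsal_column", "anterior_horn")) {
    idx <- which(truth$label_map == lab)
    for (k in 1:3)
      expect_equal(tm$eigenvalue_maps[, , k][idx],
                   rep(asg[[lab]]$eigenvalues[k], length(idx)),
                   tolerance = 1e-12)
  }
  expect_false(any(tm$clamped[which(truth$label_map != "background")]))

  # isotropic signal: FA identically zero
  iso <- lapply(asg, function(a) tissue_tensor_assignment(a$label, rep(0.4, 3)))
  tmi <- fit_tensor_map(simulate_dwi(truth, iso, supersample = 1L))
  expect_lt(max(abs(tmi$scalar_maps$FA[tmi$mask])), 1e-10)

  # signal equal to b0 in all volumes: D = 0, MD = 0
  flat <- dwi
  for (v in 2:7) flat$volumes[, , v] <- flat$volumes[, , 1]
  tmf <- fit_tensor_map(flat)
  expect_lt(max(abs(tmf$scalar_maps$MD[tmf$mask])), 1e-10)
})

test_that("scalar invariants match their definitions", {
  expect_equal(fa_from_eigenvalues(1, 1, 1), 0)
  expect_equal(fa_from_eigenvalues(1, 0, 0), 1)
  expect_equal(fa_from_eigenvalues(0, 0, 0), 0)  # 0/0 defined as 0

  # healthy-control pyramidal-tract eigenvalues: the printed AD/RD pair
  # gives the printed MD; the eigenvalue FA (0.6746, frozen from an
  # independent evaluation of the formula) deliberately exceeds the
  # printed ROI-mean FA 0.54, which averages per-pixel FA, not
  # eigenvalues
  l <- c(0.58, 0.16, 0.16)
  expect_equal(md_from_eigenvalues(l[1], l[2], l[3]), 0.30)
  expect_equal(rd_from_eigenvalues(l[2], l[3]), 0.16)
  expect_equal(ad_from_eigenvalues(l[1]), 0.58)
  expect_equal(fa_from_eigenvalues(l[1], l[2], l[3]), 0.6746172,
               tolerance = 1e-7)

  expect_error(fa_from_eigenvalues(1, 0.5, -0.1), "non-negative")
  expect_error(fa_from_eigenvalues(0.1, 0.5, 0.2), "sorted")
})

test_that("MD = (AD + 2 RD) / 3 holds pixelwise on noisy fits", {
  spec <- small_spec(snr = 15, seed = 2)
  tm <- fit_tensor_map(simulate_dwi(make_cord_geometry(spec)))
  md <- tm$scalar_maps$MD[tm$mask]
  ad <- tm$scalar_maps$AD[tm$mask]
  rd <- tm$scalar_maps$RD[tm$mask]
  expect_equal(md, (ad + 2 * rd) / 3, tolerance = 1e-12)
  expect_true(all(tm$scalar_maps$FA[tm$mask] >= 0 &
                  tm$scalar_maps$FA[tm$mask] <= 1))
})

test_that("scalar maps are invariant to in-plane rotation of the axis", {
  spec <- small_spec()
  truth <- make_cord_geometry(spec)
  base <- lapply(default_tissue_tensors(), function(a)
    tissue_tensor_assignment(a$label, a$eigenvalues, c(1, 0, 0)))
  rot <- lapply(default_tissue_tensors(), function(a)
    tissue_tensor_assignment(a$label, a$eigenvalues,
                             c(cos(0.6), sin(0.6), 0)))
  tm1 <- fit_tensor_map(simulate_dwi(truth, base, supersample = 1L))
  tm2 <- fit_tensor_map(simulate_dwi(truth, rot, supersample = 1L))
  for (m in c("FA", "MD", "RD", "AD"))
    expect_equal(tm1$scalar_maps[[m]][tm1$mask],
                 tm2$scalar_maps[[m]][tm2$mask], tolerance = 1e-9)
})

test_that("metric-map upsampling is geometric and reproduces linears", {
  cst <- matrix(2.5, 12, 12)
  up <- interpolate_map(cst, 0.78125, 0.2)
  expect_equal(dim(up$map), rep(ceiling(12 * 0.78125 / 0.2), 2))
  expect_equal(max(abs(up$map - 2.5)), 0, tolerance = 1e-12)

  # a linear ramp passes through bicubic interpolation unchanged
  r_mm <- (seq_len(12) - 0.5) * 0.78125
  ramp <- outer(r_mm, r_mm, function(a, b) 0.3 * a + 0.1 * b)
  upr <- interpolate_map(ramp, 0.78125, 0.2)
  ro <- upr$origin_mm[1] + (seq_len(nrow(upr$map)) - 0.5) * 0.2
  co <- upr$origin_mm[2] + (seq_len(ncol(upr$map)) - 0.5) * 0.2
  expect_equal(upr$map, outer(ro, co, function(a, b) 0.3 * a + 0.1 * b),
               tolerance = 1e-6)

  expect_error(interpolate_map(cst, 0.78125, 0), "positive")
  expect_error(interpolate_map(cst, 0.1, 0.2), "exceed")
})

test_that("ROI FA bias stays small at acquisition-like noise", {
  asg <- default_tissue_tensors()
  biases <- c()
  for (s in 1:5) {
    spec <- phantom_spec(snr = 20, seed = 100 + s)
    res <- suppressWarnings(run_subject(simulate_dwi(make_cord_geometry(spec)),
                                        "p"))
    expect_false(is.null(res$roi_means))
    for (rg in names(region_label))
      biases <- c(biases, bilateral_roi_mean(res$roi_means, rg, "FA") -
                    truth_region_value(asg, region_label[[rg]], "FA"))
  }
  expect_lt(median(abs(biases)), 0.03)
})
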