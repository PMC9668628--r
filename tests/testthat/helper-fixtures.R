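# Shared phantom fixtures, built once per test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# full-size noiseless phantom run end to end
noiseless_run <- function() fixture("noiseless_run", {
  spec <- phantom_spec()
  truth <- make_cord_geometry(spec)
  dwi <- simulate_dwi(truth)
  res <- suppressWarnings(run_subject(dwi, "phantom"))
  list(spec = spec, truth = truth, dwi = dwi, res = res)
})

# compact phantom (same pixel size, smaller field) for cheaper tests
small_spec <- function(...) phantom_spec(matrix_size = 64L, fov_mm = 50, ...)

region_label <- c(PT = "lateral_column_PT", DC = "dorsal_column",
                  AH = "anterior_horn")

bilateral_roi_mean <- function(roi_means, region, metric) {
  mean(roi_means[paste(region, metric, c("L", "R"), sep = "_")])
}

write_phantom_files <- function(dwi, dir, id) {
  paths <- file.path(dir, paste0(id, c(".nii.gz", ".bvec", ".bval")))
  write_dwi(dwi, paths[1], paths[2], paths[3])
  stats::setNames(as.list(paths), c("dwi", "bvec", "bval"))
}
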