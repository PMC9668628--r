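# Digital phantom of an axial C2 cord slice: elliptical cord inside a
# CSF ring, left-right symmetric "butterfly" gray matter (two tapered
# posterior-horn wedges, two anterior-horn blobs, central commissure),
# white matter partitioned into anatomical columns by angular sector.
# Angles follow the pipeline convention: degrees from the anterior
# midline, increasing toward subject-left, in [0, 360).

phantom_labels <- c("background", "csf", "anterior_horn", "posterior_horn",
                    "dorsal_column", "lateral_column_PT", "anterior_column",
                    "other_WM")

# mean over non-overlapping ss x ss blocks
block_mean <- function(x, ss) {
  n <- nrow(x) / ss; m <- ncol(x) / ss
  y <- array(x, c(ss, n, ss, m))
  matrix(colMeans(aperm(y, c(1, 3, 2, 4)), dims = 2), n, m)
}

#' Phantom specification
#'
#' Geometry, signal and noise parameters of the digital cord phantom.
#' Defaults emulate the C2 acquisition: 128 x 128 matrix, 100 x 100 mm^2
#' field of view (0.78125 mm pixels), 5 mm slice.
#'
#' @param matrix_size pixels per side (>= 32).
#' @param fov_mm field of view in mm.
#' @param slice_thickness_mm slice thickness in mm.
#' @param cord_semi_axes_mm cord semi-axes (left-right, anterior-posterior)
#'   in mm; C2 cord is roughly 13 x 8 mm across.
#' @param gm_template named list of gray-matter figure parameters:
#'   `ph_angle_deg` posterior-horn exit angle from the posterior midline,
#'   `ph_len_frac` horn tip radius as fraction of the cord boundary,
#'   `ph_width_mm` horn base width, `ph_taper` fractional width loss
#'   from base to tip (mild by default so the horn centreline, not the
#'   taper, defines the angular landmark), `ah_angle_deg` anterior-horn centre
#'   angle from the anterior midline, `ah_center_frac` anterior-horn
#'   centre radius fraction, `ah_semi_axes_mm` anterior-horn blob
#'   semi-axes (lateral, anterior-posterior), `bridge_semi_axes_mm`
#'   central commissure semi-axes.
#' @param csf_ring_width_mm width of the CSF ring around the cord.
#' @param s0_per_tissue named numeric of baseline (b0) signal per tissue
#'   class; names must cover all phantom labels.
#' @param snr baseline white-matter signal over the noise standard
#'   deviation of a single acquisition; `Inf` disables noise.
#' @param n_averages number of averaged acquisitions (default 16). A
#'   cardiac-triggered multi-minute protocol for seven single-slice
#'   volumes acquires each volume many times; the stored image is the
#'   average of the Rician magnitudes, so the effective SNR is about
#'   `snr * sqrt(n_averages)`.
#' @param shift_per_volume_px anterior-posterior displacement per volume
#'   in pixels (length = volume count of `scheme`).
#' @param seed integer RNG seed.
#' @param scheme a [gradient_scheme()]; default [default_scheme()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix_size = 128L,
                         fov_mm = 100,
                         slice_thickness_mm = 5,
                         cord_semi_axes_mm = c(6.5, 4),
                         gm_template = list(),
                         csf_ring_width_mm = 1.6,
                         s0_per_tissue = NULL,
                         snr = Inf,
                         n_averages = 16L,
                         shift_per_volume_px = NULL,
                         seed = 1L,
                         scheme = default_scheme()) {
  gm <- utils::modifyList(list(ph_angle_deg = 35, ph_len_frac = 0.92,
                               ph_width_mm = 1.4, ph_taper = 0,
                               ah_angle_deg = 33, ah_center_frac = 0.6,
                               ah_semi_axes_mm = c(1.1, 0.9),
                               bridge_semi_axes_mm = c(1.7, 0.9)),
                          gm_template)
  if (is.null(s0_per_tissue))
    s0_per_tissue <- c(background = 0.05, csf = 1.0, anterior_horn = 0.62,
                       posterior_horn = 0.62, dorsal_column = 0.58,
                       lateral_column_PT = 0.58, anterior_column = 0.58,
                       other_WM = 0.58)
  if (is.null(shift_per_volume_px))
    shift_per_volume_px <- rep(0, n_volumes(scheme))
  spec <- structure(list(matrix_size = as.integer(matrix_size),
                         fov_mm = fov_mm,
                         slice_thickness_mm = slice_thickness_mm,
                         cord_semi_axes_mm = cord_semi_axes_mm,
                         gm_template = gm,
                         csf_ring_width_mm = csf_ring_width_mm,
                         s0_per_tissue = s0_per_tissue,
                         snr = snr,
                         n_averages = as.integer(n_averages),
                         shift_per_volume_px = shift_per_volume_px,
                         seed = as.integer(seed),
                         scheme = scheme),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$matrix_size < 32L) stop("matrix_size must be >= 32")
  outer_r <- max(spec$cord_semi_axes_mm) + spec$csf_ring_width_mm
  if (2 * outer_r >= spec$fov_mm)
    stop("cord plus CSF ring does not fit inside the field of view")
  if (any(spec$cord_semi_axes_mm <= 0)) stop("cord semi-axes must be positive")
  if (length(spec$shift_per_volume_px) != n_volumes(spec$scheme))
    stop(sprintf("shift list length (%d) must equal volume count (%d)",
                 length(spec$shift_per_volume_px), n_volumes(spec$scheme)))
  if (!(spec$snr > 0)) stop("snr must be positive")
  if (is.null(spec$n_averages) || spec$n_averages < 1L)
    stop("n_averages must be a positive integer")
  miss <- setdiff(phantom_labels, names(spec$s0_per_tissue))
  if (length(miss))
    stop("s0_per_tissue lacks tissue class(es): ", paste(miss, collapse = ", "))
  invisible(spec)
}

#' Tissue tensor assignment
#'
#' @param label tissue / region name (one of the phantom labels).
#' @param eigenvalues sorted eigenvalues (l1 >= l2 >= l3 >= 0) in
#'   10^-3 mm^2/s.
#' @param principal_axis unit 3-vector of the l1 axis (scanner frame;
#'   default along z, the cord axis).
#' @return An object of class `tissue_tensor`, carrying the 3 x 3 tensor
#'   in `$D` (10^-3 mm^2/s).
#' @export
tissue_tensor_assignment <- function(label, eigenvalues,
                                     principal_axis = c(0, 0, 1)) {
  ev <- as.numeric(eigenvalues)
  if (length(ev) != 3L || any(diff(ev) > 0) || ev[3] < 0)
    stop("eigenvalues must be three values sorted descending, >= 0")
  u <- principal_axis / sqrt(sum(principal_axis^2))
  # deterministic orthonormal completion
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- c(u[2] * ref[3] - u[3] * ref[2],
          u[3] * ref[1] - u[1] * ref[3],
          u[1] * ref[2] - u[2] * ref[1])
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(u[2] * e2[3] - u[3] * e2[2],
          u[3] * e2[1] - u[1] * e2[3],
          u[1] * e2[2] - u[2] * e2[1])
  D <- ev[1] * tcrossprod(u) + ev[2] * tcrossprod(e2) + ev[3] * tcrossprod(e3)
  structure(list(label = label, eigenvalues = ev, principal_axis = u, D = D),
            class = "tissue_tensor")
}

#' Default tensor assignments per tissue class
#'
#' White-matter column tensors reproduce healthy-control axial/radial
#' diffusivity pairs (pyramidal tract 0.58/0.16, dorsal column 0.58/0.15,
#' all in 10^-3 mm^2/s) with the principal axis along the cord (z); gray
#' matter uses the lower-anisotropy anterior-horn pair 0.42/0.22 (FA
#' about 0.38); CSF is isotropic at 3.0; background is isotropic low.
#'
#' @return Named list of [tissue_tensor_assignment()]s covering every
#'   phantom label.
#' @export
default_tissue_tensors <- function() {
  z <- c(0, 0, 1)
  list(
    background        = tissue_tensor_assignment("background", rep(0.3, 3), z),
    csf               = tissue_tensor_assignment("csf", rep(3.0, 3), z),
    anterior_horn     = tissue_tensor_assignment("anterior_horn", c(0.42, 0.22, 0.22), z),
    posterior_horn    = tissue_tensor_assignment("posterior_horn", c(0.42, 0.22, 0.22), z),
    dorsal_column     = tissue_tensor_assignment("dorsal_column", c(0.58, 0.15, 0.15), z),
    lateral_column_PT = tissue_tensor_assignment("lateral_column_PT", c(0.58, 0.16, 0.16), z),
    anterior_column   = tissue_tensor_assignment("anterior_column", c(0.58, 0.16, 0.16), z),
    other_WM          = tissue_tensor_assignment("other_WM", c(0.58, 0.16, 0.16), z)
  )
}

#' Build the phantom label map and ground truth
#'
#' Rasterises the cord geometry at pixel centres. The construction uses
#' only the unsigned lateral offset, so the label map is exactly
#' left-right mirror symmetric. White matter is partitioned by angular
#' sector: anterior column (within 50 degrees of the anterior midline),
#' anterolateral white matter (50-90), lateral column / pyramidal tract
#' (90 up to the posterior-horn angle), dorsal column (between the
#' posterior horns).
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_truth`: list with `label_map`
#'   (character matrix), `landmark_angles_deg` (midline, transversal,
#'   posterior_horns, anterior_horns), `true_shifts_px`, `spec`, and
#'   `pixel_spacing_mm`.
#' @export
make_cord_geometry <- function(spec) {
  validate_phantom_spec(spec)
  lab <- raster_labels(spec, spec$matrix_size)
  gm <- spec$gm_template
  structure(list(
    label_map = lab,
    landmark_angles_deg = list(
      midline = 0,
      transversal = 90,
      posterior_horns = c(left = 180 - gm$ph_angle_deg,
                          right = 180 + gm$ph_angle_deg),
      anterior_horns = c(left = gm$ah_angle_deg,
                         right = 360 - gm$ah_angle_deg)),
    true_shifts_px = spec$shift_per_volume_px,
    pixel_spacing_mm = rep(spec$fov_mm / spec$matrix_size, 2),
    seed = spec$seed,
    spec = spec), class = "phantom_truth")
}

# rasterise the tissue labels on an n x n pixel-centre grid
raster_labels <- function(spec, n) {
  h <- spec$fov_mm / n
  a <- spec$cord_semi_axes_mm[1]   # lateral semi-axis
  b <- spec$cord_semi_axes_mm[2]   # anterior-posterior semi-axis
  gm <- spec$gm_template

  # pixel-centre offsets from the grid centre; the lateral offset is
  # computed from an integer that negates exactly under mirroring
  i <- seq_len(n); j <- seq_len(n)
  dr <- matrix(((2 * i - 1 - n) / 2) * h, n, n)          # + = posterior
  dc <- matrix(((2 * j - 1 - n) / 2) * h, n, n, byrow = TRUE)  # + = left
  s <- abs(dc)

  lab <- matrix("background", n, n)
  in_csf <- (dc / (a + spec$csf_ring_width_mm))^2 +
            (dr / (b + spec$csf_ring_width_mm))^2 <= 1
  in_cord <- (dc / a)^2 + (dr / b)^2 <= 1
  lab[in_csf] <- "csf"

  # white-matter sectors by unsigned angle from the anterior midline
  th <- atan2(s, -dr) * 180 / pi      # 0 anterior .. 180 posterior
  ph <- gm$ph_angle_deg
  lab[in_cord] <- "other_WM"
  lab[in_cord & th < 50] <- "anterior_column"
  lab[in_cord & th >= 90 & th < 180 - ph] <- "lateral_column_PT"
  lab[in_cord & th >= 180 - ph] <- "dorsal_column"

  # central commissure (gray matter bridging the two sides)
  bridge <- (s / gm$bridge_semi_axes_mm[1])^2 +
            (dr / gm$bridge_semi_axes_mm[2])^2 <= 1
  lab[in_cord & bridge] <- "anterior_horn"

  # anterior horns: blobs centred along the +-ah_angle directions
  alpha <- gm$ah_angle_deg * pi / 180
  r_ah <- gm$ah_center_frac / sqrt((sin(alpha) / a)^2 + (cos(alpha) / b)^2)
  ah0_s <- r_ah * sin(alpha); ah0_r <- -r_ah * cos(alpha)
  ah <- ((s - ah0_s) / gm$ah_semi_axes_mm[1])^2 +
        ((dr - ah0_r) / gm$ah_semi_axes_mm[2])^2 <= 1
  lab[in_cord & ah] <- "anterior_horn"

  # posterior horns: tapered wedges from the centre toward the boundary
  phi <- ph * pi / 180
  r_bnd <- 1 / sqrt((sin(phi) / a)^2 + (cos(phi) / b)^2)
  len <- gm$ph_len_frac * r_bnd
  t_ax <- dr * cos(phi) + s * sin(phi)        # along-horn distance
  q_ax <- abs(-dr * sin(phi) + s * cos(phi))  # across-horn distance
  taper <- 1 - gm$ph_taper * pmax(t_ax, 0) / len
  horn <- t_ax >= 0 & t_ax <= len & q_ax <= (gm$ph_width_mm / 2) * taper
  lab[in_cord & horn] <- "posterior_horn"
  lab
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth: %d x %d px, cord %d px, horns at %.0f/%.0f deg>\n",
              nrow(x$label_map), ncol(x$label_map),
              sum(!x$label_map %in% c("background", "csf")),
              x$landmark_angles_deg$posterior_horns[1],
              x$landmark_angles_deg$posterior_horns[2]))
  invisible(x)
}

#' Simulate the DWI stack of a phantom
#'
#' Per pixel and volume the noiseless signal is
#' `S0(tissue) * exp(-b g' D g)`; the per-volume anterior-posterior
#' displacement is applied by spectral translation (exact sub-pixel
#' ground truth); Rician noise (`sqrt((S + e1)^2 + e2^2)`,
#' `e ~ N(0, sigma)`) is then applied to the magnitude with
#' `sigma = S0_whitematter / snr`. Fully reproducible for a given seed.
#'
#' @param truth a [make_cord_geometry()] result.
#' @param assignments named list of [tissue_tensor_assignment()]s, one
#'   per label occurring in the map (default [default_tissue_tensors()]).
#' @param scheme a [gradient_scheme()]; defaults to the spec's scheme.
#' @param spec a [phantom_spec()]; defaults to the spec stored in `truth`.
#' @param supersample integer edge anti-aliasing factor (default 4):
#'   tissue signals are rasterised on a grid this many times finer and
#'   box-averaged, so boundary pixels carry realistic partial-volume
#'   mixtures while interior pixels stay pure single-tissue signal.
#'   Use 1 for hard-edged pixels.
#' @return A [dwi_slice()]. Ground-truth tensors can be recovered from
#'   `truth$label_map` and `assignments`.
#' @export
simulate_dwi <- function(truth, assignments = default_tissue_tensors(),
                         scheme = NULL, spec = NULL, supersample = 4L) {
  if (is.null(spec)) spec <- truth$spec
  if (is.null(scheme)) scheme <- spec$scheme
  ss <- as.integer(supersample)
  lab_fine <- if (ss > 1L) raster_labels(spec, spec$matrix_size * ss)
              else truth$label_map
  labs <- unique(c(as.vector(truth$label_map), as.vector(lab_fine)))
  miss <- setdiff(labs, names(assignments))
  if (length(miss))
    stop("no tensor assignment for label(s): ", paste(miss, collapse = ", "))
  nv <- n_volumes(scheme)
  if (length(spec$shift_per_volume_px) != nv)
    stop("shift list length must equal volume count")
  set.seed(spec$seed)
  n <- nrow(truth$label_map)
  g <- scheme$directions; bv <- scheme$b_values
  # per-label attenuation across volumes (tensor constant within a label)
  att <- vapply(labs, function(l) {
    D <- assignments[[l]]$D * 1e-3          # mm^2/s
    exp(-bv * rowSums((g %*% D) * g))
  }, numeric(nv))                           # nv x nlabs
  s0 <- spec$s0_per_tissue[labs]
  lab_idx <- match(lab_fine, labs)
  vols <- array(0, c(n, n, nv))
  for (v in seq_len(nv)) {
    img <- matrix(s0[lab_idx] * att[v, lab_idx], n * ss, n * ss)
    if (ss > 1L)  # box-average the supersampled signal per output pixel
      img <- block_mean(img, ss)
    if (spec$shift_per_volume_px[v] != 0)
      img <- shift_rows(img, spec$shift_per_volume_px[v])
    vols[, , v] <- img
  }
  if (is.finite(spec$snr)) {
    sigma <- spec$s0_per_tissue[["lateral_column_PT"]] / spec$snr
    acc <- array(0, dim(vols))
    for (k in seq_len(spec$n_averages)) {
      e1 <- array(stats::rnorm(length(vols), 0, sigma), dim(vols))
      e2 <- array(stats::rnorm(length(vols), 0, sigma), dim(vols))
      acc <- acc + sqrt((vols + e1)^2 + e2^2)
    }
    vols <- acc / spec$n_averages
  }
  dwi_slice(vols, pixel_spacing_mm = truth$pixel_spacing_mm,
            slice_thickness_mm = spec$slice_thickness_mm, scheme = scheme)
}

#' Ground-truth scalar value of a region
#'
#' @param assignments tensor assignments as in [simulate_dwi()].
#' @param label tissue label.
#' @param metric one of FA, MD, RD, AD.
#' @return The scalar invariant of the assigned eigenvalues.
#' @export
truth_region_value <- function(assignments, label, metric) {
  ev <- assignments[[label]]$eigenvalues
  switch(metric,
         FA = fa_from_eigenvalues(ev[1], ev[2], ev[3]),
         MD = md_from_eigenvalues(ev[1], ev[2], ev[3]),
         RD = rd_from_eigenvalues(ev[2], ev[3]),
         AD = ev[1],
         stop("unknown metric: ", metric))
}

#' Simulate a cohort of per-subject ROI means
#'
#' Draws subject-level (bilateral) ROI means from normal distributions
#' with the stated group moments; left and right values are the subject
#' value plus and minus a small side deviation, so their mean reproduces
#' the drawn value exactly. Demographics are attached: healthy-control
#' ages uniform over 20-65 years, patient ages normal around 48 (the
#' study's patient median) truncated to the same range; sex drawn at the
#' study's group frequencies; SPRS, age of onset and disease duration
#' only for patients.
#'
#' @param moments data.frame with columns `group` (HC or HSP), `region`
#'   (PT, DC, AH), `metric` (FA, MD, RD, AD), `mean`, `sd` (> 0), and `n`
#'   (>= 2, constant within group).
#' @param seed integer RNG seed.
#' @param lr_sd standard deviation of the left/right side deviation
#'   (default 0.01).
#' @return A [cohort_table()].
#' @export
simulate_cohort <- function(moments, seed = 1L, lr_sd = 0.01) {
  req <- c("group", "region", "metric", "mean", "sd", "n")
  miss <- setdiff(req, names(moments))
  if (length(miss)) stop("moments lacks column(s): ", paste(miss, collapse = ", "))
  if (any(moments$sd <= 0)) stop("sd must be > 0 for every row")
  if (any(moments$n < 2)) stop("n must be >= 2 for every group")
  set.seed(seed)
  rows <- list()
  for (grp in unique(moments$group)) {
    ms <- moments[moments$group == grp, ]
    ng <- unique(ms$n)
    if (length(ng) != 1L) stop("n must be constant within a group")
    if (grp == "HC") {
      age <- round(stats::runif(ng, 20, 65))
      sex <- ifelse(stats::runif(ng) < 60 / 115, "f", "m")
      sprs <- onset <- dur <- rep(NA_real_, ng)
    } else {
      age <- round(pmin(pmax(stats::rnorm(ng, 48, 8), 20), 65))
      sex <- ifelse(stats::runif(ng) < 13 / 32, "f", "m")
      onset <- round(pmin(pmax(stats::rnorm(ng, 32, 12), 5), age - 1))
      dur <- age - onset
      sprs <- round(pmin(pmax(stats::rnorm(ng, 17.9, 8.5), 1), 52), 1)
    }
    df <- data.frame(id = sprintf("%s%03d", grp, seq_len(ng)),
                     group = grp, age = age, sex = sex, sprs = sprs,
                     age_of_onset = onset, disease_duration = dur,
                     stringsAsFactors = FALSE)
    for (k in seq_len(nrow(ms))) {
      v <- stats::rnorm(ng, ms$mean[k], ms$sd[k])
      e <- stats::rnorm(ng, 0, lr_sd)
      if (ms$metric[k] == "FA") {
        v <- pmin(pmax(v, 0), 1)
        l <- pmin(pmax(v + e, 0), 1); r <- pmin(pmax(v - e, 0), 1)
      } else {
        l <- v + e; r <- v - e
      }
      df[[paste(ms$region[k], ms$metric[k], "L", sep = "_")]] <- l
      df[[paste(ms$region[k], ms$metric[k], "R", sep = "_")]] <- r
    }
    rows[[grp]] <- df
  }
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(d) { d[setdiff(all_cols, names(d))] <- NA; d[all_cols] })
  cohort_table(do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Group moments printed for the healthy-control / patient comparison
#'
#' Convenience constructor for [simulate_cohort()]: the published group
#' means and standard deviations of FA, RD and MD in the pyramidal
#' tracts, dorsal columns and anterior horns for 115 healthy controls
#' and 32 patients.
#'
#' @return A moments data.frame.
#' @export
published_group_moments <- function() {
  rbind(
    data.frame(group = "HC", n = 115,
               region = rep(c("PT", "DC", "AH"), each = 3),
               metric = rep(c("FA", "RD", "MD"), 3),
               mean = c(0.54, 0.16, 0.30, 0.56, 0.15, 0.29, 0.37, 0.22, 0.28),
               sd   = c(0.03, 0.04, 0.04, 0.03, 0.04, 0.04, 0.04, 0.04, 0.04)),
    data.frame(group = "HSP", n = 32,
               region = rep(c("PT", "DC", "AH"), each = 3),
               metric = rep(c("FA", "RD", "MD"), 3),
               mean = c(0.49, 0.18, 0.32, 0.52, 0.15, 0.31, 0.37, 0.20, 0.29),
               sd   = c(0.04, 0.04, 0.04, 0.04, 0.04, 0.03, 0.05, 0.04, 0.03))
  )
}
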