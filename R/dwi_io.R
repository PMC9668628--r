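#' Single-slice DWI stack
#'
#' Container for one axial multi-volume diffusion acquisition. Volumes are
#' stored as a rows x cols x volumes array in image coordinates: row index
#' runs anterior to posterior (the phase/motion axis), column index runs
#' subject-right to subject-left, 0-based pixel-center physical
#' coordinates (pixel i is centred at (i + 0.5) * spacing).
#'
#' @param volumes numeric array rows x cols x volumes (a matrix is
#'   promoted to a single volume).
#' @param pixel_spacing_mm length-2 numeric (row, col) spacing in mm.
#' @param slice_thickness_mm through-plane thickness in mm.
#' @param scheme a [gradient_scheme()] with one entry per volume.
#' @return An object of class `dwi_slice`.
#' @export
dwi_slice <- function(volumes, pixel_spacing_mm, slice_thickness_mm, scheme) {
  if (is.matrix(volumes)) volumes <- array(volumes, c(dim(volumes), 1L))
  if (length(dim(volumes)) != 3L)
    stop("`volumes` must be a rows x cols x volumes array")
  pixel_spacing_mm <- rep(as.numeric(pixel_spacing_mm), length.out = 2L)
  if (any(pixel_spacing_mm <= 0) || slice_thickness_mm <= 0)
    stop("pixel spacing and slice thickness must be positive")
  if (!inherits(scheme, "gradient_scheme")) stop("`scheme` must be a gradient_scheme")
  if (dim(volumes)[3] != n_volumes(scheme))
    stop(sprintf("stack has %d volumes but the gradient scheme describes %d",
                 dim(volumes)[3], n_volumes(scheme)))
  structure(list(volumes = volumes,
                 pixel_spacing_mm = pixel_spacing_mm,
                 slice_thickness_mm = as.numeric(slice_thickness_mm),
                 scheme = scheme),
            class = "dwi_slice")
}

#' @export
print.dwi_slice <- function(x, ...) {
  d <- dim(x$volumes)
  cat(sprintf("<dwi_slice: %d x %d px, %d volumes, %.4g x %.4g mm, thk %.3g mm>\n",
              d[1], d[2], d[3], x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              x$slice_thickness_mm))
  invisible(x)
}

b0_volume <- function(dwi) {
  i <- dwi$scheme$b0_indices
  if (length(i) == 1L) dwi$volumes[, , i]
  else apply(dwi$volumes[, , i, drop = FALSE], c(1, 2), mean)
}

#' Read a single-slice DWI acquisition
#'
#' Reads a NIfTI volume stack plus its FSL-style bvec/bval gradient table.
#' The image must contain exactly one slice in the through-plane axis; the
#' in-plane rotation of the NIfTI orientation is assumed to be the
#' identity (axial acquisition), so scanner-frame and image-frame gradient
#' directions coincide up to the fixed row/column convention.
#'
#' @param nifti_path path to a .nii or .nii.gz file with dims
#'   rows x cols x 1 x volumes (or rows x cols x volumes).
#' @param bvec_path,bval_path gradient table paths.
#' @inheritParams gradient_scheme
#' @return A [dwi_slice()].
#' @export
read_dwi <- function(nifti_path, bvec_path, bval_path, b0_threshold = 50) {
  img <- RNifti::readNifti(nifti_path)
  d <- dim(img)
  if (length(d) == 4L) {
    if (d[3] != 1L)
      stop("multi-slice input: this pipeline processes a single axial slice ",
           "(third NIfTI dimension must be 1)")
    vols <- array(img, c(d[1], d[2], d[4]))
  } else if (length(d) == 3L) {
    vols <- array(img, d)
  } else {
    stop("expected a 3-D or 4-D single-slice NIfTI image")
  }
  pd <- RNifti::pixdim(img)
  scheme <- read_gradients(bvec_path, bval_path, b0_threshold)
  dwi_slice(vols, pixel_spacing_mm = pd[1:2],
            slice_thickness_mm = if (length(pd) >= 3) pd[3] else 5,
            scheme = scheme)
}

#' Write a single-slice DWI acquisition
#'
#' @param dwi a [dwi_slice()].
#' @param nifti_path output NIfTI path (.nii or .nii.gz).
#' @param bvec_path,bval_path optional gradient table paths; omitted if NULL.
#' @return Invisibly, `dwi`.
#' @export
write_dwi <- function(dwi, nifti_path, bvec_path = NULL, bval_path = NULL) {
  d <- dim(dwi$volumes)
  arr <- array(dwi$volumes, c(d[1], d[2], 1L, d[3]))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(dwi$pixel_spacing_mm, dwi$slice_thickness_mm, 1)
  RNifti::writeNifti(img, nifti_path)
  if (!is.null(bvec_path) && !is.null(bval_path))
    write_gradients(dwi$scheme, bvec_path, bval_path)
  invisible(dwi)
}

#' Write a scalar map as NIfTI
#'
#' @param map numeric matrix (rows x cols).
#' @param path output path.
#' @param spacing_mm length-2 pixel spacing in mm.
#' @param slice_thickness_mm through-plane thickness.
#' @return Invisibly, `map`.
#' @export
write_map <- function(map, path, spacing_mm, slice_thickness_mm = 5) {
  arr <- array(map, c(dim(map), 1L))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rep(spacing_mm, length.out = 2), slice_thickness_mm)
  RNifti::writeNifti(img, path)
  invisible(map)
}

roi_regions <- c("PT", "DC", "AH")
roi_sides <- c("L", "R")
roi_metrics <- c("FA", "MD", "RD", "AD")

#' Column names of the per-subject ROI means
#'
#' @return Character vector of the 24 region x metric x side columns
#'   (e.g. `"PT_FA_L"`).
#' @export
roi_mean_columns <- function() {
  as.vector(outer(outer(roi_regions, roi_metrics, paste, sep = "_"),
                  roi_sides, paste, sep = "_"))
}

#' Validate and type a cohort table
#'
#' A cohort table holds one row per subject: `id`, `group` (HC or HSP),
#' `age` (years), `sex` (f or m), optional clinical fields `sprs`,
#' `age_of_onset`, `disease_duration` (NA where not applicable, e.g. SPRS
#' for healthy controls), and per-ROI mean columns named
#' `<region>_<metric>_<side>` for region PT/DC/AH, metric FA/MD/RD/AD and
#' side L/R. FA columns must lie in [0, 1].
#'
#' @param df a data.frame.
#' @return The validated data.frame with class `cohort_table` prepended.
#' @export
cohort_table <- function(df) {
  req <- c("id", "group", "age", "sex")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("cohort table lacks required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$id))
    stop("duplicate subject ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (!all(df$group %in% c("HC", "HSP")))
    stop("unknown group label(s): ",
         paste(setdiff(unique(df$group), c("HC", "HSP")), collapse = ", "))
  if (!all(df$sex %in% c("f", "m")))
    stop("sex must be coded 'f' or 'm'")
  for (cl in c("sprs", "age_of_onset", "disease_duration"))
    if (!cl %in% names(df)) df[[cl]] <- NA_real_
  fa_cols <- intersect(grep("_FA_", names(df), value = TRUE), names(df))
  for (cl in fa_cols) {
    v <- df[[cl]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop(sprintf("column %s has FA values outside [0, 1]", cl))
  }
  class(df) <- unique(c("cohort_table", class(df)))
  df
}

#' Read / write a cohort CSV
#'
#' CSV round trips losslessly up to numeric formatting; missing clinical
#' values are empty cells.
#'
#' @param csv_path path to a cohort CSV with a header row.
#' @return [read_cohort()] returns a validated [cohort_table()];
#'   `write_cohort` invisibly returns the table.
#' @export
read_cohort <- function(csv_path) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  cohort_table(df)
}

#' @rdname read_cohort
#' @param table a [cohort_table()] (or coercible data.frame).
#' @export
write_cohort <- function(table, csv_path) {
  table <- cohort_table(as.data.frame(table))
  utils::write.csv(table, csv_path, row.names = FALSE, na = "")
  invisible(table)
}

#' Bilateral (left/right averaged) ROI means
#'
#' @param table a [cohort_table()].
#' @return The table with added `<region>_<metric>` columns, each the mean
#'   of the corresponding `_L` and `_R` columns.
#' @export
bilateral_means <- function(table) {
  for (rg in roi_regions) for (mt in roi_metrics) {
    l <- paste(rg, mt, "L", sep = "_"); r <- paste(rg, mt, "R", sep = "_")
    if (all(c(l, r) %in% names(table)))
      table[[paste(rg, mt, sep = "_")]] <- (table[[l]] + table[[r]]) / 2
  }
  table
}
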