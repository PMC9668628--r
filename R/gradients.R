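#' Diffusion gradient scheme
#'
#' A gradient scheme pairs diffusion-encoding directions (scanner frame,
#' z parallel to the cord axis) with b-values. Volumes with b below
#' `b0_threshold` are treated as unweighted (b0) reference volumes.
#'
#' @param directions numeric matrix, one row per volume, 3 columns (x, y, z).
#'   Rows of b0 volumes may be zero; weighted rows are normalised to unit
#'   length.
#' @param b_values numeric vector of b-values in s/mm^2, one per volume.
#' @param b0_threshold b-values at or below this are treated as b0
#'   (default 50 s/mm^2, the conventional tolerance for nominally
#'   unweighted volumes).
#'
#' @return An object of class `gradient_scheme`: a list with `directions`
#'   (unit rows for weighted volumes), `b_values` and `b0_indices`.
#' @export
#' @examples
#' sc <- default_scheme()
#' sc$b0_indices  # volume 1 is the unweighted reference
gradient_scheme <- function(directions, b_values, b0_threshold = 50) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L)
    stop("`directions` must have 3 columns (x, y, z)")
  if (nrow(directions) != length(b_values))
    stop(sprintf("direction count (%d) does not match b-value count (%d)",
                 nrow(directions), length(b_values)))
  if (any(!is.finite(b_values)) || any(b_values < 0))
    stop("b-values must be finite and non-negative")
  b0 <- which(b_values <= b0_threshold)
  if (length(b0) == 0L)
    stop("scheme has no b0 volume (all b-values above the b0 threshold)")
  nrm <- sqrt(rowSums(directions^2))
  wtd <- setdiff(seq_len(nrow(directions)), b0)
  if (any(nrm[wtd] == 0))
    stop("weighted volumes must have non-zero direction vectors")
  directions[wtd, ] <- directions[wtd, , drop = FALSE] / nrm[wtd]
  structure(list(directions = directions,
                 b_values = as.numeric(b_values),
                 b0_indices = b0),
            class = "gradient_scheme")
}

#' The 6-direction cervical-cord encoding scheme
#'
#' One b0 volume followed by six directions chosen so that each weighted
#' volume mixes at most two axes: (1,0,1), (-1,0,1), (0,1,1), (0,1,-1),
#' (1,1,0), (-1,1,0), in the scanner frame with z along the cord.
#'
#' @param b diffusion weighting in s/mm^2 for the six weighted volumes
#'   (default 800, typical for cervical-cord DTI at 3 T).
#' @return A [gradient_scheme()] with 7 volumes.
#' @export
default_scheme <- function(b = 800) {
  dirs <- rbind(c(0, 0, 0),
                c(1, 0, 1), c(-1, 0, 1), c(0, 1, 1),
                c(0, 1, -1), c(1, 1, 0), c(-1, 1, 0))
  gradient_scheme(dirs, c(0, rep(b, 6)))
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("<gradient_scheme: %d volumes (%d b0), b = %s s/mm2>\n",
              length(x$b_values), length(x$b0_indices),
              paste(unique(x$b_values[-x$b0_indices]), collapse = ", ")))
  invisible(x)
}

n_volumes <- function(scheme) length(scheme$b_values)

#' Read an FSL-style gradient table
#'
#' bvec files carry one line per axis (3 x N); transposed N x 3 files are
#' accepted and flipped when unambiguous. bval is a single line of N values.
#'
#' @param bvec_path,bval_path paths to plain-text gradient files.
#' @inheritParams gradient_scheme
#' @return A [gradient_scheme()].
#' @export
read_gradients <- function(bvec_path, bval_path, b0_threshold = 50) {
  bval <- scan(bval_path, what = numeric(), quiet = TRUE)
  vec <- as.matrix(utils::read.table(bvec_path))
  if (nrow(vec) == 3L && ncol(vec) != 3L) {
    vec <- t(vec)
  } else if (ncol(vec) != 3L) {
    if (nrow(vec) == 3L) vec <- t(vec)
    else stop("bvec file is neither 3 x N nor N x 3")
  } else if (nrow(vec) == 3L && ncol(vec) == 3L) {
    # 3 x 3 is ambiguous; FSL convention (rows = axes) assumed
    vec <- t(vec)
  }
  if (nrow(vec) != length(bval))
    stop(sprintf("bvec has %d directions but bval has %d values",
                 nrow(vec), length(bval)))
  dimnames(vec) <- NULL
  gradient_scheme(vec, bval, b0_threshold)
}

#' Write an FSL-style gradient table
#'
#' @param scheme a [gradient_scheme()].
#' @inheritParams read_gradients
#' @return Invisibly, the scheme.
#' @export
write_gradients <- function(scheme, bvec_path, bval_path) {
  # file rows are axes (3 x N); write() fills lines from the vector, so
  # the column-major vector of the N x 3 matrix gives the x line first
  write(scheme$directions, bvec_path, ncolumns = n_volumes(scheme))
  write(scheme$b_values, bval_path, ncolumns = n_volumes(scheme))
  invisible(scheme)
}

#' In-plane pixel spacing from acquisition geometry
#'
#' @param fov_mm field of view in mm.
#' @param matrix_size acquisition matrix size (pixels along the same axis).
#' @return Pixel spacing in mm (`fov_mm / matrix_size`); 100 mm / 128
#'   gives the 0.78 mm in-plane resolution of the C2 protocol.
#' @export
pixel_spacing_from_geometry <- function(fov_mm, matrix_size) {
  if (!is.numeric(fov_mm) || fov_mm <= 0) stop("`fov_mm` must be positive")
  if (!is.numeric(matrix_size) || matrix_size <= 0)
    stop("`matrix_size` must be positive")
  fov_mm / matrix_size
}
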