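# Cropping to the intraspinal field and anterior-posterior motion
# correction from midsagittal intensity profiles. Only the
# anterior-posterior (row) axis is corrected: it is the phase-encoding
# axis where breathing displaces the cord. No eddy-current correction is
# applied anywhere in the pipeline.

#' Translate image rows by a (sub-pixel) displacement
#'
#' @param mat numeric matrix.
#' @param shift_px signed displacement in pixels along the row
#'   (anterior to posterior) axis; positive moves content toward higher
#'   row indices.
#' @param method `"fourier"` (default): circular spectral translation via
#'   a phase ramp, exact for band-limited content and invertible;
#'   `"linear"`: linear interpolation with edge replication.
#' @return Shifted matrix of the same size.
#' @export
shift_rows <- function(mat, shift_px, method = c("fourier", "linear")) {
  method <- match.arg(method)
  if (shift_px == 0) return(mat)
  n <- nrow(mat)
  if (method == "fourier") {
    k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n]
    ph <- exp(-2i * pi * k * shift_px / n)
    if (n %% 2 == 0) ph[n / 2 + 1] <- cos(pi * shift_px)  # keep Nyquist real
    Re(stats::mvfft(stats::mvfft(mat) * ph, inverse = TRUE)) / n
  } else {
    src <- seq_len(n) - shift_px
    i0 <- pmin(pmax(floor(src), 1), n)
    i1 <- pmin(pmax(i0 + 1, 1), n)
    t <- pmin(pmax(src - floor(src), 0), 1)
    mat[i0, , drop = FALSE] * (1 - t) + mat[i1, , drop = FALSE] * t
  }
}

#' Crop a DWI stack to the intraspinal field
#'
#' All volumes are cropped identically; pixel geometry is preserved. In
#' `"auto"` mode the box is derived from the bright CSF ring on the b0
#' image: intensity thresholding (Otsu), largest connected component,
#' bounding box plus a margin.
#'
#' @param dwi a [dwi_slice()].
#' @param bbox either `"auto"` or an integer vector
#'   `(row0, row1, col0, col1)`, 0-based half-open (so `(0, 10, 0, 10)`
#'   selects a 10 x 10 field).
#' @param margin_px margin added around the detected component in auto
#'   mode (default 4, leaving room for breathing displacement of the
#'   cord within the box).
#' @return The cropped [dwi_slice()], with the box stored in attribute
#'   `"bbox"`.
#' @export
crop_to_intraspinal <- function(dwi, bbox = "auto", margin_px = 4L) {
  d <- dim(dwi$volumes)
  if (identical(bbox, "auto")) {
    b0 <- b0_volume(dwi)
    thr <- otsu_threshold(b0)
    m <- b0 > thr
    if (!any(m))
      stop("auto crop failed: no foreground above the Otsu threshold; ",
           "pass a manual bbox")
    lab <- label_components(m)
    big <- which.max(tabulate(lab[lab > 0]))
    idx <- which(lab == big, arr.ind = TRUE)
    bbox <- c(max(min(idx[, 1]) - 1L - margin_px, 0L),
              min(max(idx[, 1]) + margin_px, d[1]),
              max(min(idx[, 2]) - 1L - margin_px, 0L),
              min(max(idx[, 2]) + margin_px, d[2]))
  }
  bbox <- as.integer(bbox)
  if (length(bbox) != 4L) stop("bbox must be (row0, row1, col0, col1)")
  if (bbox[1] < 0 || bbox[3] < 0 || bbox[2] > d[1] || bbox[4] > d[2])
    stop("bbox lies outside the image grid")
  if (bbox[2] <= bbox[1] || bbox[4] <= bbox[3]) stop("bbox is empty")
  out <- dwi
  out$volumes <- dwi$volumes[(bbox[1] + 1L):bbox[2],
                             (bbox[3] + 1L):bbox[4], , drop = FALSE]
  attr(out, "bbox") <- bbox
  out
}

# Otsu's threshold on a numeric matrix, on the original intensity scale
otsu_threshold <- function(x) {
  r <- range(x, finite = TRUE)
  if (r[1] == r[2]) return(r[1])
  thr <- EBImage::otsu(EBImage::Image((x - r[1]) / (r[2] - r[1])),
                       range = c(0, 1))
  r[1] + thr * (r[2] - r[1])
}

# connected-component labelling of a logical matrix
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
}

#' Midsagittal intensity profile
#'
#' Mean intensity over a vertical band of columns centred on the image
#' midline, one value per row. Fractional border columns of the band are
#' weighted by their overlap so the band stays symmetric about the
#' midline for any grid parity.
#'
#' @param volume numeric matrix (rows = anterior to posterior).
#' @param band_width_px band width in pixels (default 5).
#' @param center_col band centre in pixel units from the left edge;
#'   defaults to the image midline `ncol / 2`.
#' @return Numeric vector of length `nrow(volume)`.
#' @export
midsagittal_profile <- function(volume, band_width_px = 5, center_col = NULL) {
  m <- ncol(volume)
  if (band_width_px > m) stop("band is wider than the image")
  if (is.null(center_col)) center_col <- m / 2
  lo <- center_col - band_width_px / 2
  hi <- center_col + band_width_px / 2
  if (lo < 0 || hi > m) stop("band extends outside the image")
  # column j (1-based) covers [j-1, j]
  w <- pmax(0, pmin(seq_len(m), hi) - pmax(seq_len(m) - 1, lo))
  as.vector(volume %*% w) / sum(w)
}

#' Estimate anterior-posterior displacement between two profiles
#'
#' Maximises the normalised cross-correlation between `profile` and
#' `reference_profile` over integer lags in `[-max_shift_px,
#' max_shift_px]` (non-circular, overlapping segments), then refines to
#' sub-pixel precision by parabolic interpolation of the correlation
#' peak. Positive output means `profile` is displaced toward higher row
#' indices (posterior) relative to the reference.
#'
#' @param profile,reference_profile numeric vectors of equal length.
#' @param max_shift_px integer search bound (default 10).
#' @return Displacement in pixels, with logical attribute `"at_bound"`
#'   set when the correlation peak sits on the search boundary (the
#'   estimate is then unreliable).
#' @export
estimate_ap_shift <- function(profile, reference_profile, max_shift_px = 10L) {
  n <- length(profile)
  if (length(reference_profile) != n) stop("profiles differ in length")
  max_shift_px <- as.integer(max_shift_px)
  if (max_shift_px < 1L || max_shift_px >= n - 2L)
    stop("max_shift_px out of range for this profile length")
  lags <- -max_shift_px:max_shift_px
  cc <- vapply(lags, function(d) {
    if (d >= 0) { a <- profile[(1 + d):n]; b <- reference_profile[1:(n - d)] }
    else        { a <- profile[1:(n + d)]; b <- reference_profile[(1 - d):n] }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  if (all(is.na(cc)))
    stop("flat (zero-variance) profile: correlation undefined")
  k <- which.max(cc)
  at_bound <- k == 1L || k == length(lags)
  est <- lags[k]
  if (!at_bound && !anyNA(cc[(k - 1):(k + 1)])) {
    y1 <- cc[k - 1]; y2 <- cc[k]; y3 <- cc[k + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) est <- lags[k] + 0.5 * (y1 - y3) / den
  }
  structure(est, at_bound = at_bound)
}

# centre of mass of a profile after floor subtraction; insensitive to
# the contrast polarity difference between b0 (bright CSF) and weighted
# (dark CSF) volumes, because both profiles are centred on the cord
profile_com <- function(p) {
  q <- pmax(p - stats::median(p), 0)
  if (sum(q) == 0) stop("flat profile: centre of mass undefined")
  sum(seq_along(q) * q) / sum(q)
}

#' Correct anterior-posterior motion against the b0 volume
#'
#' Each weighted volume's midsagittal profile is aligned to the b0
#' profile and the volume translated by minus the estimated shift
#' (spectral translation by default). The b0 volume is never altered.
#' The default estimator is the difference of the profiles' floored
#' centres of mass, which is insensitive to the opposite CSF contrast
#' of b0 and diffusion-weighted volumes; `estimator = "ncc"` uses
#' [estimate_ap_shift()] directly (appropriate when reference and
#' target share contrast).
#'
#' @param dwi a [dwi_slice()] containing a b0 volume.
#' @param max_shift_px displacement bound; estimates beyond it are
#'   flagged unreliable (and, for `"ncc"`, bound the lag search).
#' @param band_width_px band width for [midsagittal_profile()].
#' @param method translation method, see [shift_rows()].
#' @param estimator `"com"` (default) or `"ncc"`.
#' @param min_shift_px optional dead band (default 0, correct always):
#'   when positive, estimates below it are recorded but not applied.
#'   Note that a dead band can leave volumes inconsistently corrected
#'   when estimates straddle it; it is useful mainly for QC reruns.
#' @return List with `dwi` (corrected stack) and `shifts`, a data.frame
#'   (volume, shift_px, applied, at_bound, is_b0) for QC; reference (b0)
#'   volumes have shift 0 by definition.
#' @export
motion_correct <- function(dwi, max_shift_px = 10L, band_width_px = 5,
                           method = c("fourier", "linear"),
                           estimator = c("com", "ncc"),
                           min_shift_px = 0) {
  method <- match.arg(method)
  estimator <- match.arg(estimator)
  ref <- midsagittal_profile(b0_volume(dwi), band_width_px)
  ref_com <- if (estimator == "com") profile_com(ref)
  nv <- n_volumes(dwi$scheme)
  b0 <- dwi$scheme$b0_indices
  shifts <- numeric(nv); bound <- logical(nv); applied <- logical(nv)
  out <- dwi
  for (v in setdiff(seq_len(nv), b0)) {
    p <- midsagittal_profile(dwi$volumes[, , v], band_width_px)
    if (estimator == "com") {
      shifts[v] <- profile_com(p) - ref_com
      bound[v] <- abs(shifts[v]) > max_shift_px
    } else {
      s <- estimate_ap_shift(p, ref, max_shift_px)
      shifts[v] <- as.numeric(s)
      bound[v] <- attr(s, "at_bound")
    }
    applied[v] <- abs(shifts[v]) > min_shift_px
    if (applied[v])
      out$volumes[, , v] <- shift_rows(dwi$volumes[, , v], -shifts[v], method)
  }
  list(dwi = out,
       shifts = data.frame(volume = seq_len(nv), shift_px = shifts,
                           applied = applied, at_bound = bound,
                           is_b0 = seq_len(nv) %in% b0))
}
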