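# Semi-automated geometry-based ROI method: a sampling ellipse is fitted
# to the cord on the FA map, the FA is read out along the ellipse at 600
# angular samples (0.6 degree steps), the gray-matter troughs of that
# profile locate the posterior horns, and six circular ROIs (pyramidal
# tract, dorsal column, anterior horn; left and right) are placed at
# angular positions derived from the landmarks.
#
# Angle convention: degrees from the anterior midline, increasing toward
# subject-left, range [0, 360). Physical coordinates are (row_mm,
# col_mm) with the pixel-centre convention.

norm_angle <- function(a) ((a %% 360) + 360) %% 360

#' Sampling ellipse on the cord
#'
#' @param center_mm physical centre (row_mm, col_mm).
#' @param semi_axes_mm (a, b): long axis along the transversal
#'   (left-right) direction, short axis anterior-posterior; `a >= b > 0`.
#' @param rotation_deg in-plane tilt of the long axis relative to the
#'   left-right axis (positive rotates the left end toward anterior).
#' @param midline_angle_deg,transversal_angle_deg,posterior_horn_angles_deg
#'   landmark angles, NA until detected.
#' @param anterior_horn_angles_deg anterior-horn trough angles, NA until
#'   detected.
#' @return An object of class `cord_ellipse`.
#' @export
cord_ellipse <- function(center_mm, semi_axes_mm, rotation_deg = 0,
                         midline_angle_deg = NA_real_,
                         transversal_angle_deg = NA_real_,
                         posterior_horn_angles_deg = c(NA_real_, NA_real_),
                         anterior_horn_angles_deg = c(NA_real_, NA_real_)) {
  if (semi_axes_mm[2] <= 0 || semi_axes_mm[1] < semi_axes_mm[2])
    stop("semi-axes must satisfy a >= b > 0")
  structure(list(center_mm = as.numeric(center_mm),
                 semi_axes_mm = as.numeric(semi_axes_mm),
                 rotation_deg = as.numeric(rotation_deg),
                 midline_angle_deg = midline_angle_deg,
                 transversal_angle_deg = transversal_angle_deg,
                 posterior_horn_angles_deg = posterior_horn_angles_deg,
                 anterior_horn_angles_deg = anterior_horn_angles_deg),
            class = "cord_ellipse")
}

#' @export
print.cord_ellipse <- function(x, ...) {
  cat(sprintf("<cord_ellipse: centre (%.2f, %.2f) mm, axes %.2f x %.2f mm, tilt %.1f deg>\n",
              x$center_mm[1], x$center_mm[2], x$semi_axes_mm[1],
              x$semi_axes_mm[2], x$rotation_deg))
  if (!is.na(x$posterior_horn_angles_deg[1]))
    cat(sprintf("  landmarks: midline %.1f, transversal %.1f, horns %.1f / %.1f deg\n",
                x$midline_angle_deg, x$transversal_angle_deg,
                x$posterior_horn_angles_deg[1], x$posterior_horn_angles_deg[2]))
  invisible(x)
}

#' Point on the ellipse at a profile angle
#'
#' Radial parameterisation: the returned point is the intersection of the
#' ray from the ellipse centre in direction `theta` with the ellipse, so
#' angular landmarks keep their geometric meaning for any axis ratio.
#'
#' @param ellipse a [cord_ellipse()].
#' @param theta_deg angle(s) in the profile convention.
#' @return Matrix with columns `row_mm`, `col_mm`.
#' @export
ellipse_point <- function(ellipse, theta_deg) {
  th <- theta_deg * pi / 180
  rho <- ellipse$rotation_deg * pi / 180
  # direction in (X = left, Y = anterior) coordinates
  ux <- sin(th); uy <- cos(th)
  # rotate into the ellipse frame
  ex <- cos(rho) * ux + sin(rho) * uy
  ey <- -sin(rho) * ux + cos(rho) * uy
  t <- 1 / sqrt((ex / ellipse$semi_axes_mm[1])^2 +
                (ey / ellipse$semi_axes_mm[2])^2)
  cbind(row_mm = ellipse$center_mm[1] - t * uy,
        col_mm = ellipse$center_mm[2] + t * ux)
}

#' Cord mask from an FA map
#'
#' FA threshold (Otsu by default, absolute fallback available) followed
#' by selection of the largest connected component. A signal-support
#' mask should be supplied for noisy data: pure-noise background pixels
#' have high apparent FA, so the FA threshold alone cannot separate
#' cord from background at realistic SNR — but background is dark on
#' the b0 image, which the support mask encodes.
#'
#' @param fa_map numeric FA matrix.
#' @param threshold absolute FA threshold; `NULL` (default) uses Otsu's
#'   method (computed within the support when one is given).
#' @param support optional logical matrix of pixels with credible
#'   signal, e.g. `b0 > Otsu(b0)`.
#' @return Logical matrix.
#' @export
cord_mask <- function(fa_map, threshold = NULL, support = NULL) {
  x <- fa_map
  x[is.na(x)] <- 0
  if (is.null(support)) support <- !logical(length(x))
  if (max(x[support]) <= 0 || diff(range(x[support])) == 0)
    stop("empty cord mask: FA map has no contrast above background")
  if (is.null(threshold)) threshold <- otsu_threshold(x[support])
  m <- x >= threshold & support
  if (!any(m)) stop("empty cord mask: no pixels above the FA threshold")
  lab <- label_components(m)
  lab == which.max(tabulate(lab[lab > 0]))
}

#' Signal-support mask from a b0 image
#'
#' Pixels brighter than the Otsu threshold of the b0 volume (the
#' intraspinal space: CSF and cord).
#'
#' @param b0 numeric matrix.
#' @return Logical matrix.
#' @export
b0_support <- function(b0) b0 > otsu_threshold(b0)

#' Initial sampling ellipse from cord-mask moments
#'
#' Centre and axes come from the first and second spatial moments of the
#' cord mask (for a filled ellipse the semi-axis equals twice the
#' standard deviation along the principal direction); the axes are then
#' shrunk so the sampling path runs inside the cord, crossing the
#' columns and gray-matter horns.
#'
#' @param fa_map numeric FA matrix.
#' @param spacing_mm pixel spacing (scalar or pair).
#' @param shrink axis shrink factor (default 0.63).
#' @param threshold,support passed to [cord_mask()].
#' @return A [cord_ellipse()].
#' @export
init_ellipse <- function(fa_map, spacing_mm, shrink = 0.63, threshold = NULL,
                         support = NULL) {
  spacing_mm <- rep(spacing_mm, length.out = 2)
  m <- cord_mask(fa_map, threshold, support)
  idx <- which(m, arr.ind = TRUE)
  # pixel-centre physical coordinates
  r_mm <- (idx[, 1] - 0.5) * spacing_mm[1]
  c_mm <- (idx[, 2] - 0.5) * spacing_mm[2]
  ctr <- c(mean(r_mm), mean(c_mm))
  # work in (X = left, Y = anterior)
  X <- c_mm - ctr[2]; Y <- -(r_mm - ctr[1])
  cov <- stats::cov(cbind(X, Y)) * (length(X) - 1) / length(X)
  eg <- eigen(cov, symmetric = TRUE)
  axes <- 2 * sqrt(pmax(eg$values, 0))
  v <- eg$vectors[, 1]
  rot <- atan2(v[2], v[1]) * 180 / pi
  if (rot > 90) rot <- rot - 180
  if (rot <= -90) rot <- rot + 180
  cord_ellipse(center_mm = ctr,
               semi_axes_mm = shrink * axes,
               rotation_deg = rot)
}

#' Angular FA profile along the ellipse
#'
#' Bicubic sampling of the map at `n` uniformly spaced angles on the
#' ellipse (default 600, i.e. a 0.6 degree step).
#'
#' @param map numeric matrix (typically the FA map).
#' @param spacing_mm pixel spacing of `map`.
#' @param ellipse a [cord_ellipse()].
#' @param n number of angular samples (default 600).
#' @return An object of class `angular_profile`: list with `angles_deg`,
#'   `values`, `sampling_step_deg`.
#' @export
sample_profile <- function(map, spacing_mm, ellipse, n = 600L) {
  spacing_mm <- rep(spacing_mm, length.out = 2)
  ang <- (seq_len(n) - 1) * 360 / n
  pts <- ellipse_point(ellipse, ang)
  ext <- dim(map) * spacing_mm
  if (any(pts[, 1] < 0) || any(pts[, 2] < 0) ||
      any(pts[, 1] > ext[1]) || any(pts[, 2] > ext[2]))
    stop("ellipse exits the map grid")
  structure(list(angles_deg = ang,
                 values = sample_map_mm(map, spacing_mm, pts[, 1], pts[, 2]),
                 sampling_step_deg = 360 / n),
            class = "angular_profile")
}

#' @export
print.angular_profile <- function(x, ...) {
  cat(sprintf("<angular_profile: %d samples, step %.2f deg, range %.3f-%.3f>\n",
              length(x$values), x$sampling_step_deg,
              min(x$values), max(x$values)))
  invisible(x)
}

# circular moving average over w samples (w odd)
smooth_circular <- function(v, w = 15L) {
  n <- length(v); k <- w %/% 2
  vv <- c(v[(n - k + 1):n], v, v[1:k])
  as.vector(stats::filter(vv, rep(1 / w, w), sides = 2))[(k + 1):(k + n)]
}

# indices of strict local minima of a circular sequence
circular_minima <- function(v) {
  n <- length(v)
  prev <- c(v[n], v[-n]); nxt <- c(v[-1], v[1])
  which(v < prev & v <= nxt)
}

# profile-contrast objective: the smoothed profile should be bright
# where the white-matter columns cross the midlines and the transversal
# line (sectors around 0, 90, 180, 270 degrees) and dip into gray
# matter in the four quadrants between them. Each quadrant trough is
# scored against the mean of its two flanking white-matter peaks; using
# local flanks (not the global maximum) keeps the optimum centred on a
# symmetric cord.
profile_contrast <- function(profile, smooth_w = 15L) {
  sm <- smooth_circular(profile$values, smooth_w)
  ang <- profile$angles_deg
  sector_max <- function(c0, hw = 15) {
    d <- abs(((ang - c0 + 180) %% 360) - 180)
    max(sm[d <= hw])
  }
  wm <- c(a = sector_max(0), l = sector_max(90),
          p = sector_max(180), r = sector_max(270))
  trough <- function(lo, hi) min(sm[ang >= lo & ang <= hi])
  (wm[["a"]] + wm[["l"]]) / 2 - trough(20, 70) +
    (wm[["l"]] + wm[["p"]]) / 2 - trough(100, 160) +
    (wm[["p"]] + wm[["r"]]) / 2 - trough(200, 260) +
    (wm[["r"]] + wm[["a"]]) / 2 - trough(290, 340)
}

#' Iteratively adjust the ellipse to the FA profile
#'
#' Coordinate-wise pattern search over centre, semi-axes and rotation
#' maximising the profile-contrast objective (sum over the four expected
#' gray-matter troughs of white-matter peak minus trough). Only
#' improving moves are accepted, so the objective is non-decreasing;
#' steps are halved when no move improves, and the search stops when the
#' relative improvement falls below `tol`, the steps become negligible,
#' or after `max_iter` sweeps.
#'
#' @param map FA map.
#' @param spacing_mm pixel spacing.
#' @param ellipse initial [cord_ellipse()].
#' @param max_iter maximum parameter sweeps (default 50).
#' @param tol relative objective-change tolerance (default 1e-4).
#' @param smooth_w smoothing window (samples) for the objective.
#' @param bounds list of search bounds around the anchor ellipse:
#'   `center_mm` maximal centre displacement, `axis_frac` maximal
#'   relative semi-axis change, `rotation_deg` maximal tilt change. The
#'   search is local by design: the moment-based initial ellipse is
#'   already close, and an unconstrained contrast search can drift onto
#'   the cord/CSF boundary where interpolation overshoot inflates the
#'   apparent contrast. A previously refined ellipse remembers its
#'   anchor, so re-refinement searches the same region (and is a fixed
#'   point) instead of creeping.
#' @return The refined [cord_ellipse()] with attributes `"objective"`,
#'   `"converged"` and `"anchor"`.
#' @export
refine_ellipse <- function(map, spacing_mm, ellipse, max_iter = 50L,
                           tol = 1e-4, smooth_w = 15L,
                           bounds = list(center_mm = 0.15, axis_frac = 0.1,
                                         rotation_deg = 5)) {
  obj_of <- function(e) {
    tryCatch(profile_contrast(sample_profile(map, spacing_mm, e),
                              smooth_w),
             error = function(err) -Inf)
  }
  anchor <- attr(ellipse, "anchor")
  if (is.null(anchor))
    anchor <- c(ellipse$center_mm, ellipse$semi_axes_mm, ellipse$rotation_deg)
  lo <- c(anchor[1:2] - bounds$center_mm, anchor[3:4] * (1 - bounds$axis_frac),
          anchor[5] - bounds$rotation_deg)
  hi <- c(anchor[1:2] + bounds$center_mm, anchor[3:4] * (1 + bounds$axis_frac),
          anchor[5] + bounds$rotation_deg)
  par <- c(ellipse$center_mm, ellipse$semi_axes_mm, ellipse$rotation_deg)
  make_e <- function(p) {
    if (any(p < lo) || any(p > hi)) return(NULL)
    if (p[4] <= 0.5 || p[3] < p[4]) return(NULL)
    cord_ellipse(p[1:2], p[3:4], p[5])
  }
  obj <- obj_of(ellipse)
  steps <- c(0.2, 0.2, 0.2, 0.2, 1)      # mm, mm, mm, mm, degrees
  min_steps <- c(0.02, 0.02, 0.02, 0.02, 0.2)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    improved <- FALSE
    for (k in seq_along(par)) for (sgn in c(-1, 1)) {
      p2 <- par; p2[k] <- p2[k] + sgn * steps[k]
      e2 <- make_e(p2)
      if (is.null(e2)) next
      o2 <- obj_of(e2)
      # only significant gains are accepted: sub-tolerance wiggles of
      # the interpolated objective must not walk a symmetric solution
      # off the symmetric optimum
      if (o2 > obj + tol * max(abs(obj), 1e-12)) {
        improved <- TRUE; par <- p2; obj <- o2
      }
    }
    if (!improved) {
      if (all(steps <= min_steps)) { converged <- TRUE; break }
      steps <- pmax(steps / 2, min_steps)
    }
  }
  out <- make_e(par)
  if (!converged)
    warning("ellipse refinement did not fully converge; returning best so far")
  attr(out, "objective") <- obj
  attr(out, "converged") <- converged
  attr(out, "anchor") <- anchor
  out
}

#' Detect midline, transversal line and posterior-horn angles
#'
#' The midline is the axis minimising left-right asymmetry of the
#' profile; the transversal line is the direction of the cord mask's
#' maximal width through the ellipse centre (falling back to midline +
#' 90 when no mask is supplied); the posterior-horn exit angles are the
#' deepest local minima of the smoothed profile on each posterior side
#' of the midline. Anterior-horn angles (deepest anterior-quadrant
#' minima) are detected alongside for ROI placement.
#'
#' @param profile an [sample_profile()] result on the refined ellipse.
#' @param ellipse the refined [cord_ellipse()].
#' @param mask optional logical cord mask for the transversal search.
#' @param spacing_mm pixel spacing of `mask`.
#' @param smooth_w smoothing window in samples (default 15, i.e. 9
#'   degrees at the 0.6 degree step) applied before minima detection.
#' @param min_depth minimum FA depth of an acceptable trough below the
#'   window's peak (default 0.05): a cord without gray-matter contrast
#'   produces only numerical wiggles, which must not be mistaken for
#'   horns.
#' @param symmetrize treat the horn exit angles as a symmetric pair
#'   about the midline (default TRUE): the left and right angular
#'   deviations are averaged, matching the mirror-symmetric butterfly
#'   model of the gray matter and roughly halving the angular noise.
#'   Set FALSE to keep the two troughs fully independent (e.g. for
#'   visibly asymmetric cords).
#' @return The ellipse with landmark fields filled.
#' @export
detect_landmarks <- function(profile, ellipse, mask = NULL,
                             spacing_mm = NULL, smooth_w = 15L,
                             min_depth = 0.05, symmetrize = TRUE) {
  v <- profile$values
  n <- length(v)
  if (max(v) - min(v) < 1e-9)
    stop("landmark failure: profile is flat, no gray-matter troughs")
  # midline: minimise sum of squared left-right differences of the
  # smoothed profile over candidate axes within +-30 degrees of anterior
  vs <- smooth_circular(v, smooth_w)
  cand <- which(profile$angles_deg <= 30 | profile$angles_deg >= 330)
  asym <- vapply(cand, function(k) {
    d <- seq_len(n %/% 2 - 1)
    left <- vs[((k - 1 + d) %% n) + 1]
    right <- vs[((k - 1 - d) %% n) + 1]
    mean((left - right)^2)
  }, numeric(1))
  midline <- profile$angles_deg[cand[which.min(asym)]]

  # transversal line: maximal cord width through the ellipse centre
  if (!is.null(mask)) {
    spacing_mm <- rep(spacing_mm, length.out = 2)
    idx <- which(mask, arr.ind = TRUE)
    ctr <- c(mean((idx[, 1] - 0.5) * spacing_mm[1]),
             mean((idx[, 2] - 0.5) * spacing_mm[2]))
    psis <- seq(60, 120, by = 0.5) + midline
    widths <- vapply(psis, function(psi) {
      chord_length(mask, spacing_mm, ctr, psi)
    }, numeric(1))
    # pixelation flattens the maximum into a plateau; take its centre
    transversal <- norm_angle(stats::median(psis[widths == max(widths)]))
  } else {
    transversal <- norm_angle(midline + 90)
  }

  sm <- smooth_circular(v, smooth_w)
  mins <- circular_minima(sm)
  rel <- norm_angle(profile$angles_deg[mins] - midline)
  relall <- norm_angle(profile$angles_deg - midline)
  # the deepest local minimum per window, refined to the centroid of its
  # trough (samples below a depth threshold): partial volume flattens
  # the gray-matter troughs, so a raw argmin wanders under noise while
  # the trough centroid stays put
  step <- profile$sampling_step_deg
  pick <- function(lo, hi) {
    inwin <- relall > lo & relall < hi
    sel <- mins[rel > lo & rel < hi]
    if (length(sel) == 0L) return(NA_real_)
    k <- sel[which.min(sm[sel])]
    if (sm[k] > max(sm[inwin]) - min_depth) return(NA_real_)
    thr <- sm[k] + 0.25 * (max(sm[inwin]) - sm[k])
    idx <- which(inwin & sm < thr)
    ord <- idx[order(relall[idx])]
    rel_ord <- relall[ord]
    pos <- which(ord == k)
    lo_i <- pos; hi_i <- pos
    while (lo_i > 1 && rel_ord[lo_i] - rel_ord[lo_i - 1] <= 1.5 * step)
      lo_i <- lo_i - 1
    while (hi_i < length(ord) && rel_ord[hi_i + 1] - rel_ord[hi_i] <= 1.5 * step)
      hi_i <- hi_i + 1
    run <- ord[lo_i:hi_i]
    w <- thr - sm[run]
    norm_angle(midline + sum(w * relall[run]) / sum(w))
  }
  horn_left <- pick(95, 175)    # posterior-left
  horn_right <- pick(185, 265)  # posterior-right
  if (is.na(horn_left) || is.na(horn_right))
    stop("landmark failure: fewer than two posterior profile minima; ",
         "supply manual horn angles")
  ah_left <- pick(5, 85)        # anterior-left
  ah_right <- pick(275, 355)    # anterior-right
  if (symmetrize) {
    dev <- (norm_angle(180 - (horn_left - midline)) +
            norm_angle((horn_right - midline) - 180)) / 2
    horn_left <- norm_angle(midline + 180 - dev)
    horn_right <- norm_angle(midline + 180 + dev)
    if (!is.na(ah_left) && !is.na(ah_right)) {
      adev <- (norm_angle(ah_left - midline) +
               norm_angle(midline - ah_right)) / 2
      ah_left <- norm_angle(midline + adev)
      ah_right <- norm_angle(midline - adev)
    }
  }

  ellipse$midline_angle_deg <- norm_angle(midline)
  ellipse$transversal_angle_deg <- transversal
  ellipse$posterior_horn_angles_deg <- c(left = horn_left, right = horn_right)
  ellipse$anterior_horn_angles_deg <- c(left = ah_left, right = ah_right)
  ellipse
}

# length of the mask chord through `center_mm` along direction psi (deg)
chord_length <- function(mask, spacing_mm, center_mm, psi, step_mm = 0.2) {
  th <- psi * pi / 180
  dirv <- c(-cos(th), sin(th))  # (row, col) direction
  ext <- dim(mask) * spacing_mm
  tmax <- sqrt(sum(ext^2))
  ts <- seq(-tmax, tmax, by = step_mm)
  r <- center_mm[1] + ts * dirv[1]
  cc <- center_mm[2] + ts * dirv[2]
  ok <- r >= 0 & r < ext[1] & cc >= 0 & cc < ext[2]
  inside <- logical(length(ts))
  ri <- pmin(pmax(ceiling(r[ok] / spacing_mm[1]), 1), nrow(mask))
  ci <- pmin(pmax(ceiling(cc[ok] / spacing_mm[2]), 1), ncol(mask))
  inside[ok] <- mask[cbind(ri, ci)]
  # longest run through t = 0
  k0 <- which.min(abs(ts))
  if (!inside[k0]) return(0)
  lo <- k0; while (lo > 1 && inside[lo - 1]) lo <- lo - 1
  hi <- k0; while (hi < length(ts) && inside[hi + 1]) hi <- hi + 1
  (hi - lo) * step_mm
}

# point at fraction f of the shorter arc from angle a to angle b
frac_angle <- function(a, b, f = 0.5) {
  d <- ((b - a + 540) %% 360) - 180
  norm_angle(a + f * d)
}
mid_angle <- function(a, b) frac_angle(a, b, 0.5)

#' Place the six circular ROIs from the landmarks
#'
#' Dorsal-column ROIs sit between the posterior midline and each
#' posterior-horn angle, at fraction `dc_frac` of that arc from the
#' midline (default 0.15: the dorsal columns hug the posterior median
#' sulcus, and staying clear of the horn gray matter limits partial
#' volume); pyramidal-tract ROIs midway (`pt_frac`) between each
#' posterior-horn angle and the transversal line; anterior-horn ROIs at
#' the anterior-quadrant profile minima. ROI centres are snapped to the
#' nearest pixel centre of the fine (interpolated) grid; membership is
#' all fine-grid pixels whose centres lie within `diameter_mm / 2` of
#' the ROI centre (21 pixels for the default 1.05 mm diameter on the
#' 0.2 mm grid).
#'
#' @param ellipse a [cord_ellipse()] with landmarks filled.
#' @param grid_dim dimensions of the fine metric-map grid.
#' @param grid_spacing_mm spacing of that grid (default 0.2).
#' @param diameter_mm ROI diameter (default 1.05).
#' @param mask optional logical cord mask on the fine grid; member pixels
#'   outside it are clipped with a warning.
#' @param dc_frac,pt_frac arc fractions of the DC and PT ROI centres
#'   (see above).
#' @param origin_mm physical position of the fine grid's corner (see
#'   [interpolate_map()]); default `c(0, 0)`.
#' @return An object of class `roi_set`: data.frame (region, side,
#'   angle_deg, center_row_mm, center_col_mm, n_px) with a list column
#'   `pixels` of index matrices into the fine grid.
#' @export
place_rois <- function(ellipse, grid_dim, grid_spacing_mm = 0.2,
                       diameter_mm = 1.05, mask = NULL,
                       dc_frac = 0.15, pt_frac = 0.5,
                       origin_mm = c(0, 0)) {
  if (is.na(ellipse$midline_angle_deg) ||
      is.na(ellipse$transversal_angle_deg) ||
      anyNA(ellipse$posterior_horn_angles_deg))
    stop("landmarks must be detected before ROI placement")
  if (anyNA(ellipse$anterior_horn_angles_deg))
    stop("landmark failure: anterior-horn angles missing")
  pm <- norm_angle(ellipse$midline_angle_deg + 180)
  tl <- ellipse$transversal_angle_deg            # subject-left direction
  tr <- norm_angle(tl + 180)                     # subject-right direction
  hl <- ellipse$posterior_horn_angles_deg[["left"]]
  hr <- ellipse$posterior_horn_angles_deg[["right"]]
  ang <- c(DC_L = frac_angle(pm, hl, dc_frac), DC_R = frac_angle(pm, hr, dc_frac),
           PT_L = frac_angle(hl, tl, pt_frac), PT_R = frac_angle(hr, tr, pt_frac),
           AH_L = ellipse$anterior_horn_angles_deg[["left"]],
           AH_R = ellipse$anterior_horn_angles_deg[["right"]])
  pts <- ellipse_point(ellipse, ang)
  # snap to the nearest fine-grid pixel centre
  snap <- function(x, o) o + (round((x - o) / grid_spacing_mm - 0.5) + 0.5) *
    grid_spacing_mm
  ctr_r <- snap(pts[, 1], origin_mm[1]); ctr_c <- snap(pts[, 2], origin_mm[2])
  rad <- diameter_mm / 2
  k <- floor(rad / grid_spacing_mm)
  off <- expand.grid(dr = -k:k, dc = -k:k)
  off <- off[off$dr^2 + off$dc^2 <= (rad / grid_spacing_mm)^2, ]
  rois <- data.frame(region = sub("_.*", "", names(ang)),
                     side = sub(".*_", "", names(ang)),
                     angle_deg = as.numeric(ang),
                     center_row_mm = ctr_r, center_col_mm = ctr_c,
                     n_px = NA_integer_, stringsAsFactors = FALSE)
  pixels <- vector("list", nrow(rois))
  for (q in seq_len(nrow(rois))) {
    ri <- round((ctr_r[q] - origin_mm[1]) / grid_spacing_mm + 0.5) + off$dr
    ci <- round((ctr_c[q] - origin_mm[2]) / grid_spacing_mm + 0.5) + off$dc
    keep <- ri >= 1 & ri <= grid_dim[1] & ci >= 1 & ci <= grid_dim[2]
    if (!all(keep))
      warning(sprintf("%s_%s ROI clipped at the map border",
                      rois$region[q], rois$side[q]))
    px <- cbind(row = ri[keep], col = ci[keep])
    if (!is.null(mask)) {
      inside <- mask[px]
      if (!all(inside))
        warning(sprintf("%s_%s ROI extends outside the cord mask; clipped",
                        rois$region[q], rois$side[q]))
      px <- px[inside, , drop = FALSE]
    }
    if (nrow(px) == 0L)
      stop(sprintf("empty ROI %s_%s after clipping", rois$region[q], rois$side[q]))
    pixels[[q]] <- px
    rois$n_px[q] <- nrow(px)
  }
  rois$pixels <- pixels
  structure(rois, class = c("roi_set", class(rois)))
}

#' ROI means of the scalar maps
#'
#' Arithmetic mean of each interpolated metric map over each ROI's
#' member pixels, plus bilateral rows (mean of the left and right
#' side values).
#'
#' @param maps named list of interpolated scalar matrices (FA, MD, RD,
#'   AD), all on the ROI grid.
#' @param rois a [place_rois()] result.
#' @return Data.frame (region, side, metric, mean); side `"bilateral"`
#'   rows hold `(L + R) / 2`.
#' @export
roi_stats <- function(maps, rois) {
  out <- do.call(rbind, lapply(seq_len(nrow(rois)), function(q) {
    px <- rois$pixels[[q]]
    if (nrow(px) == 0L) stop("empty ROI")
    data.frame(region = rois$region[q], side = rois$side[q],
               metric = names(maps),
               mean = vapply(maps, function(m) mean(m[px]), numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  bi <- do.call(rbind, lapply(split(out, list(out$region, out$metric)),
    function(d) data.frame(region = d$region[1], side = "bilateral",
                           metric = d$metric[1], mean = mean(d$mean),
                           stringsAsFactors = FALSE)))
  rownames(bi) <- NULL
  rbind(out, bi)
}

#' Plot the angular FA profile with landmarks (QC figure)
#'
#' @param profile an [sample_profile()] result.
#' @param ellipse optional landmark-filled [cord_ellipse()]; landmark
#'   angles are drawn as vertical guides.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `profile`.
#' @export
plot_profile <- function(profile, ellipse = NULL, ...) {
  graphics::plot(profile$angles_deg, profile$values, type = "l",
                 xlab = "angle from anterior midline (deg)", ylab = "FA",
                 ...)
  graphics::lines(profile$angles_deg, smooth_circular(profile$values),
                  col = "gray50", lty = 2)
  if (!is.null(ellipse) && !anyNA(ellipse$posterior_horn_angles_deg)) {
    graphics::abline(v = ellipse$posterior_horn_angles_deg, col = "darkgreen")
    graphics::abline(v = ellipse$anterior_horn_angles_deg, col = "red")
    graphics::abline(v = c(ellipse$midline_angle_deg,
                           norm_angle(ellipse$midline_angle_deg + 180)),
                     col = "gray30", lty = 3)
  }
  invisible(profile)
}
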