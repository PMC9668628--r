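#' Design matrix of the log-linear tensor fit
#'
#' Maps the 7 unknowns (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz, ln S0) to log
#' signals: each volume contributes the row
#' `[-b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz, 1]`.
#'
#' @param scheme a [gradient_scheme()] with normalised directions.
#' @return Numeric matrix, one row per volume, 7 columns.
#' @export
build_design <- function(scheme) {
  g <- scheme$directions
  b <- scheme$b_values
  X <- cbind(-b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3], 1)
  if (qr(X)$rank < 7L)
    stop("degenerate gradient scheme: design matrix has rank < 7, ",
         "the tensor is not identifiable")
  X
}

#' Fit the diffusion tensor per pixel
#'
#' Per-pixel log-linear least squares on the volume stack. With exactly 7
#' volumes (one b0 + six directions) the system is exactly determined and
#' the solve is exact for noiseless data. Pixels with non-positive signal
#' in any volume are excluded from the mask. Negative eigenvalues are
#' clamped to zero and flagged rather than discarded (single-slice data
#' cannot spare pixels).
#'
#' @param dwi a [dwi_slice()] with at least 7 volumes including a b0.
#' @return An object of class `tensor_maps`: list with `tensor_map`
#'   (rows x cols x 6 array of Dxx, Dyy, Dzz, Dxy, Dxz, Dyz in
#'   10^-3 mm^2/s), `eigenvalue_maps` (rows x cols x 3, sorted
#'   descending), `scalar_maps` (list FA, MD, RD, AD), `mask`, `clamped`
#'   (logical map of pixels with clamped eigenvalues), `spacing_mm`.
#' @export
fit_tensor_map <- function(dwi) {
  if (n_volumes(dwi$scheme) < 7L)
    stop("tensor fit needs at least 7 volumes (1 b0 + 6 directions)")
  X <- build_design(dwi$scheme)
  d <- dim(dwi$volumes)
  nr <- d[1]; nc <- d[2]; nv <- d[3]
  sig <- matrix(dwi$volumes, nr * nc, nv)       # pixels x volumes
  mask <- rowSums(sig > 0) == nv
  tensor <- array(NA_real_, c(nr, nc, 6))
  evals <- array(NA_real_, c(nr, nc, 3))
  clamped <- matrix(FALSE, nr, nc)
  fa <- md <- rd <- ad <- matrix(NA_real_, nr, nc)
  if (any(mask)) {
    beta <- qr.coef(qr(X), t(log(sig[mask, , drop = FALSE])))  # 7 x npix
    Dmu <- t(beta[1:6, , drop = FALSE]) * 1e3   # npix x 6, 10^-3 mm^2/s
    idx <- which(mask)
    ev <- matrix(0, length(idx), 3)
    cl <- logical(length(idx))
    for (p in seq_along(idx)) {
      dd <- Dmu[p, ]
      Dm <- matrix(c(dd[1], dd[4], dd[5],
                     dd[4], dd[2], dd[6],
                     dd[5], dd[6], dd[3]), 3, 3)
      lam <- eigen(Dm, symmetric = TRUE, only.values = TRUE)$values
      cl[p] <- lam[3] < 0
      ev[p, ] <- pmax(lam, 0)
    }
    for (k in 1:6) tensor[, , k][idx] <- Dmu[, k]
    for (k in 1:3) evals[, , k][idx] <- ev[, k]
    clamped[idx] <- cl
    fa[idx] <- fa_from_eigenvalues(ev[, 1], ev[, 2], ev[, 3])
    md[idx] <- md_from_eigenvalues(ev[, 1], ev[, 2], ev[, 3])
    rd[idx] <- rd_from_eigenvalues(ev[, 2], ev[, 3])
    ad[idx] <- ev[, 1]
  }
  structure(list(tensor_map = tensor,
                 eigenvalue_maps = evals,
                 scalar_maps = list(FA = fa, MD = md, RD = rd, AD = ad),
                 mask = matrix(mask, nr, nc),
                 clamped = clamped,
                 spacing_mm = dwi$pixel_spacing_mm),
            class = "tensor_maps")
}

#' @export
print.tensor_maps <- function(x, ...) {
  cat(sprintf("<tensor_maps: %d x %d px, %d in mask, %d clamped>\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), sum(x$clamped)))
  invisible(x)
}

#' Scalar invariants from sorted eigenvalues
#'
#' FA = sqrt(3/2) * sqrt(sum((lambda_i - mean)^2)) / sqrt(sum(lambda_i^2));
#' MD = mean(lambda); AD = lambda1; RD = (lambda2 + lambda3) / 2. FA of
#' the all-zero tensor is defined as 0 (the formula is 0/0). Inputs must
#' be sorted descending and non-negative (clamping happens in the fit).
#'
#' @param l1,l2,l3 eigenvalue vectors, sorted `l1 >= l2 >= l3 >= 0`.
#' @return Numeric vector of the invariant.
#' @export
fa_from_eigenvalues <- function(l1, l2, l3) {
  if (any(l3 < 0) || any(l2 < l3) || any(l1 < l2))
    stop("eigenvalues must be sorted descending and non-negative")
  mb <- (l1 + l2 + l3) / 3
  num <- (l1 - mb)^2 + (l2 - mb)^2 + (l3 - mb)^2
  den <- l1^2 + l2^2 + l3^2
  out <- sqrt(1.5) * sqrt(ifelse(den > 0, num / den, 0))
  out[den == 0] <- 0
  out
}

#' @rdname fa_from_eigenvalues
#' @export
md_from_eigenvalues <- function(l1, l2, l3) (l1 + l2 + l3) / 3

#' @rdname fa_from_eigenvalues
#' @export
rd_from_eigenvalues <- function(l2, l3) (l2 + l3) / 2

#' @rdname fa_from_eigenvalues
#' @export
ad_from_eigenvalues <- function(l1, ...) l1

#' Upsample a metric map to a finer grid
#'
#' Bicubic (Catmull-Rom) interpolation onto a pixel-center-aligned grid.
#' Metric maps are interpolated after the tensor fit (never the raw DWI);
#' the default 0.2 mm target matches the ROI-placement grid.
#'
#' @param map numeric matrix.
#' @param spacing_mm source pixel spacing (scalar or (row, col) pair).
#' @param target_spacing_mm output spacing, default 0.2 mm; must not
#'   exceed the source spacing.
#' @return List with `map` (upsampled matrix), `spacing_mm`, and
#'   `origin_mm`: the output grid is centred on the source image (pixel
#'   `(i, j)` of the output sits at `origin_mm + (i - 0.5) *
#'   target_spacing_mm`), so a left-right symmetric source stays
#'   symmetric on the fine grid.
#' @export
interpolate_map <- function(map, spacing_mm, target_spacing_mm = 0.2) {
  spacing_mm <- rep(spacing_mm, length.out = 2)
  if (target_spacing_mm <= 0) stop("target spacing must be positive")
  if (any(target_spacing_mm > spacing_mm))
    stop("target spacing must not exceed the source spacing")
  n_out <- ceiling(dim(map) * spacing_mm / target_spacing_mm)
  origin <- (dim(map) * spacing_mm - n_out * target_spacing_mm) / 2
  ur <- (origin[1] + (seq_len(n_out[1]) - 0.5) * target_spacing_mm) /
    spacing_mm[1] - 0.5
  uc <- (origin[2] + (seq_len(n_out[2]) - 0.5) * target_spacing_mm) /
    spacing_mm[2] - 0.5
  Rop <- interp_operator_1d(nrow(map), ur)
  Cop <- interp_operator_1d(ncol(map), uc)
  list(map = Rop %*% map %*% t(Cop),
       spacing_mm = rep(target_spacing_mm, 2),
       origin_mm = origin)
}

# sample a map at physical (row_mm, col_mm) positions, pixel-center
# convention: pixel i is centred at (i + 0.5) * spacing
sample_map_mm <- function(map, spacing_mm, row_mm, col_mm) {
  spacing_mm <- rep(spacing_mm, length.out = 2)
  interp_bicubic_idx(map, row_mm / spacing_mm[1] - 0.5,
                     col_mm / spacing_mm[2] - 0.5)
}
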