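# Bicubic (Catmull-Rom) interpolation on pixel-center-aligned grids.
# Borders are extended linearly so that linear ramps are reproduced
# exactly everywhere, including in the extrapolation strip between the
# outermost pixel centers and the image edge.

cubic_weights <- function(t) {
  # Catmull-Rom / Keys (a = -1/2) kernel weights for the 4 neighbours
  # f[-1], f[0], f[1], f[2] at fractional offset t in [0, 1)
  t2 <- t * t; t3 <- t2 * t
  cbind(0.5 * (-t3 + 2 * t2 - t),
        0.5 * (3 * t3 - 5 * t2 + 2),
        0.5 * (-3 * t3 + 4 * t2 + t),
        0.5 * (t3 - t2))
}

pad_linear <- function(map, k = 2L) {
  n <- nrow(map); m <- ncol(map)
  out <- matrix(0, n + 2 * k, m + 2 * k)
  out[(k + 1):(k + n), (k + 1):(k + m)] <- map
  for (j in seq_len(k)) {  # rows
    out[k + 1 - j, ] <- (1 + j) * out[k + 1, ] - j * out[k + 2, ]
    out[k + n + j, ] <- (1 + j) * out[k + n, ] - j * out[k + n - 1, ]
  }
  for (j in seq_len(k)) {  # columns (after rows, so corners are bilinear)
    out[, k + 1 - j] <- (1 + j) * out[, k + 1] - j * out[, k + 2]
    out[, k + m + j] <- (1 + j) * out[, k + m] - j * out[, k + m - 1]
  }
  out
}

# Sample `map` at continuous 0-based pixel-index coordinates (ri, ci).
# Points may lie slightly outside the grid; values come from the linear
# border extension.
interp_bicubic_idx <- function(map, ri, ci) {
  if (length(ri) != length(ci)) stop("coordinate vectors differ in length")
  k <- 2L
  pad <- pad_linear(map, k)
  i0 <- floor(ri); j0 <- floor(ci)
  wr <- cubic_weights(ri - i0); wc <- cubic_weights(ci - j0)
  out <- numeric(length(ri))
  for (a in 1:4) {
    rowi <- i0 + (a - 2L) + k + 1L
    rowi <- pmin(pmax(rowi, 1L), nrow(pad))
    acc <- numeric(length(ri))
    for (b in 1:4) {
      colj <- j0 + (b - 2L) + k + 1L
      colj <- pmin(pmax(colj, 1L), ncol(pad))
      acc <- acc + wc[, b] * pad[cbind(rowi, colj)]
    }
    out <- out + wr[, a] * acc
  }
  out
}

# Dense separable interpolation operator: maps n_in input samples to
# values at continuous 0-based indices `u` (one row per output sample),
# including the 2-sample linear border extension.
interp_operator_1d <- function(n_in, u) {
  k <- 2L
  n_pad <- n_in + 2L * k
  i0 <- floor(u)
  w <- cubic_weights(u - i0)
  op <- matrix(0, length(u), n_pad)
  for (a in 1:4) {
    idx <- pmin(pmax(i0 + (a - 2L) + k + 1L, 1L), n_pad)
    op[cbind(seq_along(u), idx)] <- op[cbind(seq_along(u), idx)] + w[, a]
  }
  # fold the padded columns back onto the linear-extension stencil
  fold <- matrix(0, n_pad, n_in)
  fold[cbind(k + seq_len(n_in), seq_len(n_in))] <- 1
  for (j in seq_len(k)) {
    fold[k + 1 - j, 1] <- 1 + j;     fold[k + 1 - j, 2] <- -j
    fold[k + n_in + j, n_in] <- 1 + j; fold[k + n_in + j, n_in - 1] <- -j
  }
  op %*% fold
}
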