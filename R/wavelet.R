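# bior4.4 (CDF 9/7) lifting constants.  Subbands are rescaled so the lowpass
# DC gain is sqrt(2), matching the standard bior4.4 analysis filter bank; the
# lifting factorization with whole-sample symmetric boundary then coincides
# exactly with direct convolution against symmetric-extended signals.
.LIFT_A <- -1.586134342059924
.LIFT_B <- -0.052980118572961
.LIFT_G <-  0.882911075530934
.LIFT_D <-  0.443506852043971
.LIFT_K <-  1.230174104914001
.ZETA_LO <-  sqrt(2) / .LIFT_K
.ZETA_HI <- -.LIFT_K / sqrt(2)

# One lifting step along the rows of M.  phase = "odd" updates 0-based odd
# rows from their even neighbours, "even" the reverse; whole-sample symmetric
# reflection at both ends.
lift_step <- function(M, coef, phase) {
  n <- nrow(M)
  if (phase == "odd") {
    tgt <- seq(2L, n, 2L)                       # R rows of 0-based odd samples
    lo <- tgt - 1L
    hi <- c(if (length(tgt) > 1L) tgt[-length(tgt)] + 1L, n - 1L)
    M[tgt, ] <- M[tgt, , drop = FALSE] +
      coef * (M[lo, , drop = FALSE] + M[hi, , drop = FALSE])
  } else {
    tgt <- seq(1L, n - 1L, 2L)                  # 0-based even samples
    lo <- c(2L, if (length(tgt) > 1L) tgt[-1L] - 1L)
    hi <- tgt + 1L
    M[tgt, ] <- M[tgt, , drop = FALSE] +
      coef * (M[lo, , drop = FALSE] + M[hi, , drop = FALSE])
  }
  M
}

# Forward 9/7 transform of each column; returns rbind(lowpass, highpass).
lift_cols_fwd <- function(M) {
  n <- nrow(M)
  stopifnot(n %% 2L == 0L, n >= 2L)
  M <- lift_step(M, .LIFT_A, "odd")
  M <- lift_step(M, .LIFT_B, "even")
  M <- lift_step(M, .LIFT_G, "odd")
  M <- lift_step(M, .LIFT_D, "even")
  rbind(.ZETA_LO * M[seq(1L, n - 1L, 2L), , drop = FALSE],
        .ZETA_HI * M[seq(2L, n, 2L), , drop = FALSE])
}

# Inverse of lift_cols_fwd; S is rbind(lowpass, highpass).
lift_cols_inv <- function(S) {
  n <- nrow(S)
  half <- n %/% 2L
  M <- matrix(0, n, ncol(S))
  M[seq(1L, n - 1L, 2L), ] <- S[seq_len(half), , drop = FALSE] / .ZETA_LO
  M[seq(2L, n, 2L), ] <- S[half + seq_len(half), , drop = FALSE] / .ZETA_HI
  M <- lift_step(M, -.LIFT_D, "even")
  M <- lift_step(M, -.LIFT_G, "odd")
  M <- lift_step(M, -.LIFT_B, "even")
  M <- lift_step(M, -.LIFT_A, "odd")
  M
}

#' Number of dyadic decomposition levels for an image size
#'
#' `L = min(floor(log2(min(H, W))) - 2, 6)`, which guarantees a coarsest
#' approximation band of at least 4x4 — the minimum the SPIHT
#' spatial-orientation trees require.
#'
#' @param n_row,n_col image dimensions (each >= 16).
#' @return integer level count L >= 2.
#' @export
decomposition_levels <- function(n_row, n_col) {
  if (min(n_row, n_col) < 16L) {
    rgsc_error("rgsc_image_too_small", "need at least 16 pixels per side")
  }
  as.integer(min(floor(log2(min(n_row, n_col))) - 2, 6))
}

# Pad a matrix to (Hp, Wp) by whole-sample symmetric reflection at the
# bottom/right edges.
pad_wss <- function(x, Hp, Wp) {
  H <- nrow(x); W <- ncol(x)
  if (Hp > H) {
    extra <- Hp - H
    if (extra > H - 1L) rgsc_error("rgsc_image_too_small", "image too small to pad")
    x <- rbind(x, x[H - seq_len(extra), , drop = FALSE])
  }
  if (Wp > W) {
    extra <- Wp - W
    if (extra > W - 1L) rgsc_error("rgsc_image_too_small", "image too small to pad")
    x <- cbind(x, x[, W - seq_len(extra), drop = FALSE])
  }
  x
}

padded_dim <- function(d, levels) {
  unit <- 2L^(levels + 1L)          # keeps the coarsest LL even-sized
  as.integer(ceiling(d / unit) * unit)
}

#' 2-D bior4.4 wavelet analysis
#'
#' Separable L-level decomposition with whole-sample symmetric boundary
#' extension, stored in Mallat layout (coarsest approximation top-left,
#' detail bands nested).  Non-dyadic sizes are symmetric-padded to a
#' multiple of `2^(levels+1)`; the original size is kept for synthesis.
#'
#' @param img numeric or integer matrix (at least 16x16).
#' @param levels decomposition depth; defaults to [decomposition_levels()].
#' @return object of class `rgsc_pyramid`: `coeff` (padded Mallat plane),
#'   `levels`, `wavelet` ("bior4.4"), `dim` (original), `pad_dim`.
#' @export
dwt2_analyze <- function(img, levels = NULL) {
  if (!is.matrix(img) || !is.numeric(img)) {
    rgsc_error("rgsc_bad_image", "need a numeric matrix")
  }
  H <- nrow(img); W <- ncol(img)
  if (is.null(levels)) levels <- decomposition_levels(H, W)
  levels <- as.integer(levels)
  if (min(H, W) < 2L^(levels + 1L)) {
    rgsc_error("rgsc_image_too_small", "too few pixels for this level count")
  }
  Hp <- padded_dim(H, levels); Wp <- padded_dim(W, levels)
  x <- pad_wss(matrix(as.numeric(img), H, W), Hp, Wp)
  for (l in seq_len(levels)) {
    h <- Hp %/% 2L^(l - 1L); w <- Wp %/% 2L^(l - 1L)
    sub <- x[seq_len(h), seq_len(w), drop = FALSE]
    sub <- lift_cols_fwd(sub)
    sub <- t(lift_cols_fwd(t(sub)))
    x[seq_len(h), seq_len(w)] <- sub
  }
  structure(list(coeff = x, levels = levels, wavelet = "bior4.4",
                 dim = c(H, W), pad_dim = c(Hp, Wp)),
            class = "rgsc_pyramid")
}

#' 2-D bior4.4 wavelet synthesis
#'
#' Inverse of [dwt2_analyze()]; returns the real-valued image plane cropped
#' to the original dimensions.  Callers clip to \[0, 255\] and round for
#' display.
#'
#' @param pyr an `rgsc_pyramid`.
#' @return numeric matrix of the original image size.
#' @export
dwt2_synthesize <- function(pyr) {
  stopifnot(inherits(pyr, "rgsc_pyramid"))
  x <- pyr$coeff
  Hp <- pyr$pad_dim[1L]; Wp <- pyr$pad_dim[2L]
  for (l in rev(seq_len(pyr$levels))) {
    h <- Hp %/% 2L^(l - 1L); w <- Wp %/% 2L^(l - 1L)
    sub <- x[seq_len(h), seq_len(w), drop = FALSE]
    sub <- t(lift_cols_inv(t(sub)))
    sub <- lift_cols_inv(sub)
    x[seq_len(h), seq_len(w)] <- sub
  }
  x[seq_len(pyr$dim[1L]), seq_len(pyr$dim[2L]), drop = FALSE]
}

#' Quantize a wavelet pyramid to an integer coefficient plane
#'
#' Element-wise rounding half away from zero, split into magnitudes and
#' signs (zero magnitude carries sign +1).
#'
#' @param pyr an `rgsc_pyramid`.
#' @return object of class `rgsc_plane`: integer `mag`, integer `sign`
#'   (+1/-1), `levels`, `dim` (original), `pad_dim`.
#' @export
quantize_coeffs <- function(pyr) {
  stopifnot(inherits(pyr, "rgsc_pyramid"))
  x <- pyr$coeff
  mag <- floor(abs(x) + 0.5)
  sgn <- ifelse(x < 0 & mag > 0, -1L, 1L)
  storage.mode(mag) <- "integer"
  storage.mode(sgn) <- "integer"
  structure(list(mag = mag, sign = sgn, levels = pyr$levels,
                 wavelet = pyr$wavelet, dim = pyr$dim,
                 pad_dim = pyr$pad_dim),
            class = "rgsc_plane")
}

#' Rebuild a pyramid from an integer (or reconstructed) coefficient plane
#'
#' @param coeff numeric matrix of (possibly approximate) coefficient values
#'   in Mallat layout, padded size.
#' @param like an `rgsc_plane` or `rgsc_pyramid` carrying the geometry.
#' @return an `rgsc_pyramid`.
#' @export
dequantize_coeffs <- function(coeff, like) {
  structure(list(coeff = coeff, levels = like$levels, wavelet = like$wavelet,
                 dim = like$dim, pad_dim = like$pad_dim),
            class = "rgsc_pyramid")
}

#' @export
print.rgsc_pyramid <- function(x, ...) {
  cat(sprintf("%s pyramid: %dx%d (padded %dx%d), %d levels\n", x$wavelet,
              x$dim[1L], x$dim[2L], x$pad_dim[1L], x$pad_dim[2L], x$levels))
  invisible(x)
}
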