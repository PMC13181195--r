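# Container framing ("RGSC"), big-endian throughout:
#   magic "RGSC" | u8 version | u16 H | u16 W | u8 levels | u8 wavelet (0 =
#   bior4.4) | f32 bpp_roi | f32 bpp_bg | u8 b_max_roi | u8 b_max_bg (255
#   encodes -1) | u32 nbits_roi | u32 nbits_bg (exact SPIHT stream lengths,
#   needed to strip byte padding) | u32 mask RLE byte length + RLE payload
#   (u16 runs alternating zeros/ones, row-major, 65535/0 continuation; zero
#   length marks a uniform single-stream container) | u32 E_r + ROI Huffman
#   packet | u32 E_nr + background packet.

RGSC_MAGIC <- charToRaw("RGSC")
RGSC_VERSION <- 1L

# Run-length encode a logical mask row-major into u16 runs alternating
# 0-runs and 1-runs (starting with zeros); runs over 65535 are split with a
# zero-length run of the other value.
mask_rle_encode <- function(mask) {
  v <- as.integer(t(mask))
  r <- rle(v)
  runs <- integer(0)
  cur <- 0L                      # value the next emitted run counts
  for (i in seq_along(r$lengths)) {
    val <- r$values[i]
    n <- r$lengths[i]
    if (val != cur) {            # need a zero-length run of `cur`
      runs <- c(runs, 0L)
      cur <- val
    }
    while (n > 65535L) {
      runs <- c(runs, 65535L, 0L)
      n <- n - 65535L
    }
    runs <- c(runs, n)
    cur <- 1L - cur
  }
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  write_u16(con, runs)
  rawConnectionValue(con)
}

mask_rle_decode <- function(bytes, H, W) {
  if (length(bytes) %% 2L != 0L) {
    rgsc_error("rgsc_malformed_packet", "odd RLE byte count")
  }
  n <- length(bytes) %/% 2L
  runs <- vapply(seq_len(n), function(i) read_u16(bytes, 2L * i - 1L),
                 numeric(1))
  total <- sum(runs)
  if (total != H * W) {
    rgsc_error("rgsc_malformed_packet", "mask RLE does not cover the image")
  }
  vals <- rep(rep_len(c(0L, 1L), n), times = runs)
  matrix(as.logical(vals), H, W, byrow = TRUE)
}

#' Split an image into ROI and background half-images
#'
#' `roi = img` where the mask is set and 0 elsewhere; `bg` is the
#' complement, so the two halves sum to the original image.
#'
#' @param img integer matrix in \[0, 255\].
#' @param mask logical matrix of the same dimensions.
#' @return list with integer matrices `roi` and `bg`.
#' @export
split_by_mask <- function(img, mask) {
  img <- as_gray_image(img)
  mask <- as_binary_mask(mask, img)
  roi <- img; roi[!mask] <- 0L
  bg <- img; bg[mask] <- 0L
  list(roi = roi, bg = bg)
}

# Wavelet -> quantize -> SPIHT -> pack -> Huffman for one half-image.
encode_stream <- function(img, levels, budget_bits) {
  pyr <- dwt2_analyze(img, levels)
  plane <- quantize_coeffs(pyr)
  bs <- spiht_encode(plane, budget_bits)
  bytes <- pack_bits_msb(bs$bits)
  list(packet = huffman_encode(bytes), nbits = as.numeric(bs$nbits),
       b_max = bs$b_max, pad_dim = plane$pad_dim)
}

#' Compress an image with ROI-weighted bit allocation
#'
#' The mask splits the image into an ROI half and a background half; each is
#' transformed (bior4.4), quantized, SPIHT-coded against a bit budget of
#' `floor(bpp * H * W)` bits and Huffman-packed.  The mask travels in the
#' container as a run-length code.  With `uniform = TRUE` the whole image is
#' coded as a single stream at `bpp_roi` bits per pixel and no mask is
#' stored (the plain SPIHT baseline).
#'
#' If no mask is supplied, [segment_roi()] provides one.
#'
#' @param img integer matrix in \[0, 255\], at least 16x16.
#' @param mask logical ROI mask, or `NULL` to segment automatically.
#' @param bpp_roi bit rate of the ROI stream (also the uniform-mode rate).
#' @param bpp_bg bit rate of the background stream.
#' @param levels wavelet levels; default [decomposition_levels()].
#' @param uniform code the whole frame as one stream without a mask.
#' @param config segmentation configuration used when `mask` is `NULL`.
#' @return object of class `rgsc_container`.
#' @export
compress_image <- function(img, mask = NULL, bpp_roi = 1.0, bpp_bg = 0.25,
                           levels = NULL, uniform = FALSE,
                           config = seg_config()) {
  img <- as_gray_image(img, min_dim = 16L)
  H <- nrow(img); W <- ncol(img)
  if (is.null(levels)) levels <- decomposition_levels(H, W)
  if (!uniform) {
    if (is.null(mask)) mask <- segment_roi(img, config)$roi_mask
    mask <- as_binary_mask(mask, img)
    if (!(bpp_bg > 0 && bpp_bg <= bpp_roi && bpp_roi <= 8)) {
      warning("expected 0 < bpp_bg <= bpp_roi <= 8", call. = FALSE)
    }
  }

  if (uniform) {
    s_roi <- encode_stream(img, levels, floor(bpp_roi * H * W))
    s_bg <- list(packet = raw(0), nbits = 0, b_max = -1L)
    mask_bytes <- raw(0)
  } else {
    halves <- split_by_mask(img, mask)
    s_roi <- encode_stream(halves$roi, levels, floor(bpp_roi * H * W))
    s_bg <- encode_stream(halves$bg, levels, floor(bpp_bg * H * W))
    mask_bytes <- mask_rle_encode(mask)
  }

  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(RGSC_MAGIC, con)
  write_u8(con, RGSC_VERSION)
  write_u16(con, H); write_u16(con, W)
  write_u8(con, levels)
  write_u8(con, 0L)                       # wavelet id: bior4.4
  write_f32(con, bpp_roi); write_f32(con, bpp_bg)
  write_u8(con, if (s_roi$b_max < 0L) 255L else s_roi$b_max)
  write_u8(con, if (s_bg$b_max < 0L) 255L else s_bg$b_max)
  write_u32(con, s_roi$nbits); write_u32(con, s_bg$nbits)
  write_u32(con, length(mask_bytes)); writeBin(mask_bytes, con)
  write_u32(con, length(s_roi$packet)); writeBin(as.raw(s_roi$packet), con)
  write_u32(con, length(s_bg$packet))
  if (length(s_bg$packet)) writeBin(as.raw(s_bg$packet), con)

  structure(list(raw = rawConnectionValue(con),
                 H = H, W = W, levels = as.integer(levels),
                 wavelet = "bior4.4", version = RGSC_VERSION,
                 bpp_roi = bpp_roi, bpp_bg = bpp_bg,
                 uniform = uniform,
                 mask = if (uniform) NULL else mask,
                 mask_bytes = length(mask_bytes),
                 b_max_roi = s_roi$b_max, b_max_bg = s_bg$b_max,
                 nbits_roi = s_roi$nbits, nbits_bg = s_bg$nbits,
                 E_r = length(s_roi$packet), E_nr = length(s_bg$packet),
                 roi_packet = as.raw(s_roi$packet),
                 bg_packet = as.raw(s_bg$packet)),
            class = "rgsc_container")
}

#' Write a compressed container to disk
#'
#' @param container an `rgsc_container` (or its raw serialization).
#' @param path destination file (conventional extension `.rgsc`).
#' @return `path`, invisibly.
#' @export
write_rgsc <- function(container, path) {
  bytes <- if (inherits(container, "rgsc_container")) container$raw
           else as.raw(container)
  writeBin(bytes, path)
  invisible(path)
}

#' Read a compressed container from disk
#'
#' @param path an `.rgsc` file.
#' @return an `rgsc_container`.
#' @export
read_rgsc <- function(path) {
  if (!file.exists(path)) {
    rgsc_error("rgsc_io_error", paste0("no such file: ", path))
  }
  parse_container(readBin(path, "raw", n = file.size(path)))
}

parse_container <- function(bytes) {
  bytes <- as.raw(bytes)
  need <- function(k) {
    if (length(bytes) < k) {
      rgsc_error("rgsc_malformed_packet", "container truncated")
    }
  }
  need(29L)
  if (!identical(bytes[1:4], RGSC_MAGIC)) {
    rgsc_error("rgsc_malformed_packet", "bad magic; not an RGSC container")
  }
  version <- read_u8(bytes, 5L)
  H <- read_u16(bytes, 6L); W <- read_u16(bytes, 8L)
  levels <- read_u8(bytes, 10L)
  wavelet_id <- read_u8(bytes, 11L)
  if (wavelet_id != 0L) {
    rgsc_error("rgsc_malformed_packet", "unknown wavelet id")
  }
  bpp_roi <- read_f32(bytes, 12L); bpp_bg <- read_f32(bytes, 16L)
  b_max_roi <- read_u8(bytes, 20L); if (b_max_roi == 255L) b_max_roi <- -1L
  b_max_bg <- read_u8(bytes, 21L); if (b_max_bg == 255L) b_max_bg <- -1L
  nbits_roi <- read_u32(bytes, 22L)
  nbits_bg <- read_u32(bytes, 26L)
  at <- 30L
  need(33L)
  mask_len <- read_u32(bytes, at); at <- at + 4L
  need(at + mask_len - 1L)
  uniform <- mask_len == 0
  mask <- NULL
  if (!uniform) {
    mask <- mask_rle_decode(bytes[at:(at + mask_len - 1L)], H, W)
    at <- at + mask_len
  }
  need(at + 3L)
  E_r <- read_u32(bytes, at); at <- at + 4L
  need(at + E_r - 1L)
  roi_packet <- if (E_r > 0) bytes[at:(at + E_r - 1L)] else raw(0)
  at <- at + E_r
  need(at + 3L)
  E_nr <- read_u32(bytes, at); at <- at + 4L
  if (E_nr > 0) {
    need(at + E_nr - 1L)
    bg_packet <- bytes[at:(at + E_nr - 1L)]
  } else bg_packet <- raw(0)

  structure(list(raw = bytes, H = H, W = W, levels = levels,
                 wavelet = "bior4.4", version = version,
                 bpp_roi = bpp_roi, bpp_bg = bpp_bg, uniform = uniform,
                 mask = mask, mask_bytes = mask_len,
                 b_max_roi = b_max_roi, b_max_bg = b_max_bg,
                 nbits_roi = nbits_roi, nbits_bg = nbits_bg,
                 E_r = E_r, E_nr = E_nr,
                 roi_packet = roi_packet, bg_packet = bg_packet),
            class = "rgsc_container")
}

decode_stream <- function(packet, nbits, b_max, H, W, levels) {
  pad <- c(padded_dim(H, levels), padded_dim(W, levels))
  if (b_max < 0L || length(packet) == 0L) {
    plane <- matrix(0, pad[1L], pad[2L])
  } else {
    bytes <- huffman_decode(packet)
    bits <- unpack_bits_msb(bytes, nbits)
    plane <- spiht_decode(bits, dim = pad, levels = levels, b_max = b_max)
  }
  pyr <- structure(list(coeff = plane, levels = levels, wavelet = "bior4.4",
                        dim = c(H, W), pad_dim = pad),
                   class = "rgsc_pyramid")
  dwt2_synthesize(pyr)
}

#' Decompress an RGSC container
#'
#' Huffman-decodes, SPIHT-decodes and inverse-transforms each stream, then
#' fuses ROI and background through the transmitted mask; the fused plane is
#' clipped to \[0, 255\] and rounded.
#'
#' @param x an `rgsc_container`, its raw bytes, or a file path.
#' @return integer matrix in \[0, 255\].
#' @export
decompress_image <- function(x) {
  if (is.character(x)) x <- read_rgsc(x)
  if (is.raw(x)) x <- parse_container(x)
  stopifnot(inherits(x, "rgsc_container"))
  roi_hat <- decode_stream(x$roi_packet, x$nbits_roi, x$b_max_roi,
                           x$H, x$W, x$levels)
  if (x$uniform) {
    fused <- roi_hat
  } else {
    bg_hat <- decode_stream(x$bg_packet, x$nbits_bg, x$b_max_bg,
                            x$H, x$W, x$levels)
    fused <- ifelse(x$mask, roi_hat, bg_hat)
  }
  out <- round(pmin(pmax(fused, 0), 255))
  storage.mode(out) <- "integer"
  out
}

#' @export
print.rgsc_container <- function(x, ...) {
  cat(sprintf("RGSC container: %dx%d, levels %d, %s, E_r=%dB E_nr=%dB mask=%dB\n",
              x$H, x$W, x$levels,
              if (x$uniform) sprintf("uniform %.2f bpp", x$bpp_roi)
              else sprintf("roi %.2f / bg %.2f bpp", x$bpp_roi, x$bpp_bg),
              x$E_r, x$E_nr, x$mask_bytes))
  invisible(x)
}

#' Mean squared error between two images
#'
#' @param a,b numeric matrices of identical dimensions.
#' @return mean of squared pixel differences.
#' @export
img_mse <- function(a, b) {
  check_same_dim(a, b)
  mean((as.numeric(a) - as.numeric(b))^2)
}

#' Peak signal-to-noise ratio in decibels
#'
#' `10 log10(R^2 / MSE)` with peak `R = 255`; `Inf` for identical images.
#'
#' @param a,b numeric matrices of identical dimensions.
#' @param peak maximum signal value (255 for 8-bit images).
#' @return PSNR in dB.
#' @export
img_psnr <- function(a, b, peak = 255) {
  m <- img_mse(a, b)
  if (m == 0) return(Inf)
  10 * log10(peak^2 / m)
}

#' Structural similarity index
#'
#' Global-statistics SSIM with stabilizers `C1 = (0.01*255)^2` and
#' `C2 = (0.03*255)^2` by default; `method = "window"` averages the SSIM map
#' of an 11x11 Gaussian window (sigma 1.5).  Variances and the covariance
#' use the population convention.
#'
#' @param a,b numeric matrices of identical dimensions.
#' @param method `"global"` or `"window"`.
#' @return value in \[-1, 1\].
#' @export
img_ssim <- function(a, b, method = c("global", "window")) {
  check_same_dim(a, b)
  method <- match.arg(method)
  C1 <- (0.01 * 255)^2
  C2 <- (0.03 * 255)^2
  a <- matrix(as.numeric(a), nrow(a), ncol(a))
  b <- matrix(as.numeric(b), nrow(b), ncol(b))
  if (method == "global") {
    mu_a <- mean(a); mu_b <- mean(b)
    va <- mean((a - mu_a)^2); vb <- mean((b - mu_b)^2)
    cab <- mean((a - mu_a) * (b - mu_b))
    return(((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
             ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2)))
  }
  g <- outer(dnorm(-5:5, sd = 1.5), dnorm(-5:5, sd = 1.5))
  g <- g / sum(g)
  smooth <- function(x) {
    EBImage::imageData(EBImage::filter2(x, g, boundary = "replicate"))
  }
  mu_a <- smooth(a); mu_b <- smooth(b)
  va <- smooth(a * a) - mu_a^2
  vb <- smooth(b * b) - mu_b^2
  cab <- smooth(a * b) - mu_a * mu_b
  mean(((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
         ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2)))
}

#' Rate accounting of a compressed container
#'
#' With `S = H*W` bytes for an 8-bit image: `cr_r = S / E_r`,
#' `cr_nr = S / E_nr`, `cr_full = S / (E_r + E_nr + mask bytes)`, and
#' `bpp_x = 8 * bytes / S` correspondingly.  `spiht_bits_*` are the raw
#' SPIHT stream lengths before entropy coding; for a uniform container
#' `cr_spiht = 8 S / spiht bits` is the SPIHT-only compression ratio used
#' for baseline comparisons.
#'
#' @param container an `rgsc_container`.
#' @return named list of rates and ratios.
#' @export
rate_report <- function(container) {
  stopifnot(inherits(container, "rgsc_container"))
  S <- container$H * container$W
  E_r <- container$E_r; E_nr <- container$E_nr
  mb <- container$mask_bytes
  rep <- list(
    cr_r = S / E_r,
    cr_nr = if (container$uniform) NA_real_ else S / E_nr,
    cr_full = S / (E_r + E_nr + mb),
    bpp_r = 8 * E_r / S,
    bpp_nr = if (container$uniform) NA_real_ else 8 * E_nr / S,
    bpp_full = 8 * (E_r + E_nr + mb) / S,
    spiht_bits_roi = container$nbits_roi,
    spiht_bits_bg = container$nbits_bg,
    mask_bytes = mb
  )
  rep$cr_spiht <- if (container$nbits_roi > 0) {
    8 * S / (container$nbits_roi + container$nbits_bg)
  } else NA_real_
  rep
}

#' Distortion report of a reconstruction against the original
#'
#' Full-frame MSE/PSNR/SSIM, plus ROI-restricted and background-restricted
#' MSE/PSNR when a mask is given (computed over the masked pixel sets).
#'
#' @param orig,recon integer matrices in \[0, 255\].
#' @param mask optional logical ROI mask.
#' @return named list of quality metrics.
#' @export
evaluate_compression <- function(orig, recon, mask = NULL) {
  check_same_dim(orig, recon)
  out <- list(mse = img_mse(orig, recon),
              psnr = img_psnr(orig, recon),
              ssim = img_ssim(orig, recon))
  if (!is.null(mask)) {
    mask <- as_binary_mask(mask, orig)
    o <- as.numeric(orig); r <- as.numeric(recon); m <- as.vector(mask)
    region <- function(sel) {
      if (!any(sel)) return(list(mse = NA_real_, psnr = NA_real_))
      ms <- mean((o[sel] - r[sel])^2)
      list(mse = ms, psnr = if (ms == 0) Inf else 10 * log10(255^2 / ms))
    }
    roi <- region(m); bg <- region(!m)
    out$mse_roi <- roi$mse; out$psnr_roi <- roi$psnr
    out$mse_bg <- bg$mse; out$psnr_bg <- bg$psnr
  }
  out
}
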