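#' Specification for a synthetic brain-like phantom
#'
#' Describes a seeded synthetic MR slice: an elliptical head of hypointense
#' parenchyma over a dark background, one or more hyperintense elliptical
#' lesions (the ground-truth ROI), a smooth multiplicative bias field and
#' additive noise.  The lesion support is returned as an exact mask, so every
#' downstream stage can be scored without real data.
#'
#' The default intensity triplet (background 10, tissue 45, lesion 220)
#' emulates FLAIR/T2-like contrast where the lesion is the hyperintense
#' structure: that contrast regime is what makes an Otsu threshold isolate
#' the lesion and seed the region grower inside it.
#'
#' @param seed integer RNG seed; generation is bit-identical per seed.
#' @param dim image height and width in pixels.
#' @param head_axes head-ellipse semi-axes as fractions of height and width.
#' @param tumor_count number of lesions; the target area is split evenly.
#' @param tumor_area_pct target lesion area as percent of the frame (2-9
#'   covers the foreground-area range reported for real tumor data).
#' @param tumor_intensity,tissue_intensity,background_intensity plateau gray
#'   levels before bias and noise.
#' @param bias_amplitude multiplicative bias amplitude (0.10 means +/-10%).
#' @param noise_sigma additive noise standard deviation in gray levels.
#' @param noise_type `"gaussian"` (default) or `"rician"` (MR magnitude
#'   noise).
#' @return an object of class `rgsc_phantom_spec`.
#' @export
phantom_spec <- function(seed = 0L,
                         dim = c(256L, 256L),
                         head_axes = c(0.42, 0.34),
                         tumor_count = 1L,
                         tumor_area_pct = 5,
                         tumor_intensity = 220,
                         tissue_intensity = 45,
                         background_intensity = 10,
                         bias_amplitude = 0.10,
                         noise_sigma = 10,
                         noise_type = c("gaussian", "rician")) {
  noise_type <- match.arg(noise_type)
  if (tumor_area_pct <= 0 || tumor_area_pct >= 100) {
    rgsc_error("rgsc_infeasible_spec", "tumor_area_pct must be in (0, 100)")
  }
  structure(list(seed = as.integer(seed), dim = as.integer(dim),
                 head_axes = head_axes, tumor_count = as.integer(tumor_count),
                 tumor_area_pct = tumor_area_pct,
                 tumor_intensity = tumor_intensity,
                 tissue_intensity = tissue_intensity,
                 background_intensity = background_intensity,
                 bias_amplitude = bias_amplitude,
                 noise_sigma = noise_sigma, noise_type = noise_type),
            class = "rgsc_phantom_spec")
}

#' Generate a phantom image with its ground-truth ROI mask
#'
#' @param spec an [phantom_spec()] object.
#' @return list with `image` (integer matrix in \[0,255\]), `mask` (logical
#'   matrix, the exact lesion support before noise) and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "rgsc_phantom_spec"))
  H <- spec$dim[1L]; W <- spec$dim[2L]
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)

  with_seed(spec$seed, {
    hc_r <- H / 2 + runif(1, -0.02, 0.02) * H
    hc_c <- W / 2 + runif(1, -0.02, 0.02) * W
    a <- spec$head_axes[1L] * H
    b <- spec$head_axes[2L] * W
    head <- ((rr - hc_r) / a)^2 + ((cc - hc_c) / b)^2 <= 1

    target_px <- spec$tumor_area_pct / 100 * H * W
    per_tumor <- target_px / spec$tumor_count
    tumor <- matrix(FALSE, H, W)
    for (k in seq_len(spec$tumor_count)) {
      placed <- FALSE
      for (try in 1:200) {
        q <- runif(1, 0.6, 1.0)            # aspect ratio of the lesion
        theta <- runif(1, 0, pi)
        at <- sqrt(per_tumor / (pi * q))
        bt <- at * q
        tr <- runif(1, hc_r - a, hc_r + a)
        tc <- runif(1, hc_c - b, hc_c + b)
        u <- (rr - tr) * cos(theta) + (cc - tc) * sin(theta)
        v <- -(rr - tr) * sin(theta) + (cc - tc) * cos(theta)
        cand <- (u / at)^2 + (v / bt)^2 <= 1
        # must lie fully inside the head and not touch an earlier lesion
        if (any(cand) && all(head[cand]) && !any(tumor[cand])) {
          tumor <- tumor | cand
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        rgsc_error("rgsc_infeasible_spec",
                   "could not place a lesion inside the head ellipse")
      }
    }

    img <- matrix(spec$background_intensity, H, W)
    img[head] <- spec$tissue_intensity
    img[tumor] <- spec$tumor_intensity

    phi1 <- runif(1, 0, 2 * pi)
    phi2 <- runif(1, 0, 2 * pi)
    bias <- sin(pi * rr / H + phi1) * sin(pi * cc / W + phi2)
    img <- img * (1 + spec$bias_amplitude * bias)

    if (spec$noise_sigma > 0) {
      if (spec$noise_type == "gaussian") {
        img <- img + rnorm(H * W, 0, spec$noise_sigma)
      } else {
        img <- sqrt((img + rnorm(H * W, 0, spec$noise_sigma))^2 +
                      rnorm(H * W, 0, spec$noise_sigma)^2)
      }
    }
    img <- round(pmin(pmax(img, 0), 255))
    storage.mode(img) <- "integer"
    list(image = img, mask = tumor, spec = spec)
  })
}

#' Generate a deterministic batch of phantoms
#'
#' Produces `n` image/mask pairs with seeds `base_seed, ..., base_seed+n-1`,
#' all other parameters taken from `spec`.
#'
#' @param spec template [phantom_spec()].
#' @param n number of phantoms (>= 1).
#' @param base_seed seed of the first phantom; defaults to `spec$seed`.
#' @return list of `n` results of [generate_phantom()].
#' @export
phantom_batch <- function(spec = phantom_spec(), n, base_seed = spec$seed) {
  stopifnot(n >= 1)
  lapply(seq_len(n) - 1L, function(k) {
    s <- spec
    s$seed <- as.integer(base_seed + k)
    generate_phantom(s)
  })
}

#' @export
print.rgsc_phantom_spec <- function(x, ...) {
  cat(sprintf(
    "phantom spec: %dx%d, seed %d, %d lesion(s) ~%.1f%% area, noise sigma %.1f (%s)\n",
    x$dim[1L], x$dim[2L], x$seed, x$tumor_count, x$tumor_area_pct,
    x$noise_sigma, x$noise_type))
  invisible(x)
}
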