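#' Otsu threshold of an 8-bit image
#'
#' Exhaustively maximizes the between-class variance of the 256-bin
#' histogram. Pixels strictly greater than the returned threshold are
#' foreground; ties in variance are broken by the smallest threshold.
#'
#' @param img integer matrix in \[0, 255\].
#' @return integer threshold in \[0, 255\].
#' @export
otsu_threshold <- function(img) {
  img <- as_gray_image(img)
  h <- tabulate(as.vector(img) + 1L, nbins = 256L)
  if (sum(h > 0L) < 2L) {
    rgsc_error("rgsc_degenerate_histogram",
               "image is constant; no threshold separates two classes")
  }
  p <- h / sum(h)
  lev <- 0:255
  w0 <- cumsum(p)                 # class {<= t}
  mu <- cumsum(p * lev)
  mu_t <- mu[256L]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, 256L)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  as.integer(which.max(sigma_b) - 1L)   # which.max takes the first maximum
}

#' Select the region-growing seed from the Otsu foreground
#'
#' Returns the foreground pixel (intensity strictly above `t`) whose
#' intensity is closest to the mean foreground intensity; ties are broken by
#' the smallest row-major index.
#'
#' @param img integer matrix in \[0, 255\].
#' @param t intensity threshold (foreground is `img > t`).
#' @return integer vector `c(row, col)` (1-based).
#' @export
select_seed <- function(img, t) {
  img <- as_gray_image(img)
  fg <- img > t
  if (!any(fg)) {
    rgsc_error("rgsc_empty_foreground", "no pixel exceeds the threshold")
  }
  m <- mean(img[fg])
  idx <- which(fg)                           # column-major indices
  rows <- ((idx - 1L) %% nrow(img)) + 1L
  cols <- ((idx - 1L) %/% nrow(img)) + 1L
  d <- abs(img[idx] - m)
  ord <- order(d, row_major_index(rows, cols, ncol(img)))
  c(rows[ord[1L]], cols[ord[1L]])
}

#' Seeded region growing with a running-mean admission rule
#'
#' Breadth-first (FIFO) growth under 8-connectivity.  When a pixel is
#' dequeued its unvisited neighbours are examined in the fixed order
#' N, S, W, E, NW, NE, SW, SE; a neighbour is admitted iff the absolute
#' difference between its intensity and the current region mean is at most
#' `tol`, and the mean is updated immediately after each admission.  A pixel
#' rejected once is never re-examined, which makes the procedure
#' deterministic and single-pass.
#'
#' @param img integer matrix in \[0, 255\].
#' @param seed integer `c(row, col)`, 1-based, inside the image.
#' @param tol non-negative intensity tolerance.
#' @return an object of class `rgsc_region`: `mask` (logical matrix, one
#'   8-connected component containing the seed), `seed`, `region_mean`,
#'   `tolerance`.
#' @export
region_grow <- function(img, seed, tol) {
  img <- as_gray_image(img)
  seed <- as.integer(seed)
  if (length(seed) != 2L || seed[1L] < 1L || seed[1L] > nrow(img) ||
      seed[2L] < 1L || seed[2L] > ncol(img)) {
    rgsc_error("rgsc_seed_out_of_bounds", "seed must lie inside the image")
  }
  if (tol < 0) rgsc_error("rgsc_bad_argument", "tol must be >= 0")
  res <- .region_grow_cpp(img, seed[1L] - 1L, seed[2L] - 1L, as.numeric(tol))
  structure(list(mask = res$mask, seed = seed,
                 region_mean = res$mean, tolerance = tol),
            class = "rgsc_region")
}

#' Fuzzy c-means on arbitrary feature vectors
#'
#' Plain alternating-optimization FCM: memberships
#' `U_ij = 1 / sum_k (d_ij / d_kj)^(2/(p-1))` with Euclidean distances and
#' centroids `V_i = sum_j U_ij^p x_j / sum_j U_ij^p`.  A data point at zero
#' distance from a centroid receives full membership in the first such
#' cluster.  Iteration stops when the largest absolute membership change
#' falls below `tol` or after `max_iter` iterations.
#'
#' @param x numeric matrix, one data point per row.
#' @param m number of clusters (>= 2).
#' @param p fuzzifier exponent (> 1).
#' @param tol convergence tolerance on memberships.
#' @param max_iter iteration cap.
#' @param seed RNG seed for the uniform centroid initialization over the
#'   per-dimension data range.
#' @param init optional m x d matrix of initial centroids overriding the
#'   seeded initialization.
#' @return object of class `rgsc_fcm` with fields `U`, `V`, `p`, `m`,
#'   `objective_trace`, `iterations`, `converged`.
#' @export
fcm_fit <- function(x, m, p = 2, tol = 1e-5, max_iter = 200L, seed = 0L,
                    init = NULL) {
  if (p <= 1) rgsc_error("rgsc_invalid_fuzzifier", "fuzzifier p must be > 1")
  if (m < 2L) rgsc_error("rgsc_bad_argument", "need at least 2 clusters")
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  V <- if (is.null(init)) {
    lo <- apply(x, 2L, min); hi <- apply(x, 2L, max)
    with_seed(seed, matrix(runif(m * d, rep(lo, each = m), rep(hi, each = m)), m, d))
  } else {
    stopifnot(nrow(init) == m, ncol(init) == d)
    as.matrix(init)
  }

  memberships <- function(D2) {
    U <- matrix(0, n, m)
    zero <- D2 < 1e-24
    zrow <- rowSums(zero) > 0L
    if (any(zrow)) {
      first0 <- max.col(-D2[zrow, , drop = FALSE], ties.method = "first")
      U[cbind(which(zrow), first0)] <- 1
    }
    ok <- !zrow
    if (any(ok)) {
      G <- D2[ok, , drop = FALSE]^(-1 / (p - 1))
      U[ok, ] <- G / rowSums(G)
    }
    U
  }

  dist2 <- function(V) {
    D2 <- matrix(0, n, m)
    for (i in seq_len(m)) {
      D2[, i] <- rowSums((x - matrix(V[i, ], n, d, byrow = TRUE))^2)
    }
    D2
  }

  U_prev <- NULL
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    D2 <- dist2(V)
    U <- memberships(D2)
    trace <- c(trace, sum(U^p * D2))
    if (!is.null(U_prev) && max(abs(U - U_prev)) < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    U_prev <- U
    Up <- U^p
    W <- colSums(Up)
    V <- crossprod(Up, x) / ifelse(W > 0, W, 1)
  }
  structure(list(U = U, V = V, p = p, m = m, objective_trace = trace,
                 iterations = it, converged = converged),
            class = "rgsc_fcm")
}

#' Region-growing-constrained fuzzy c-means (RG-FCM)
#'
#' Clusters every pixel of the image on the 2-D feature vector
#' `(intensity, lambda * M)`, where `M` is the region-growing mask indicator.
#' The spatial constraint from region growing thus enters the FCM objective
#' as an extra Euclidean feature with weight `lambda`, keeping the standard
#' membership/centroid updates intact.
#'
#' @param img integer matrix in \[0, 255\].
#' @param rg an `rgsc_region` from [region_grow()].
#' @param clusters number of clusters m (default 2: informative vs rest).
#' @param fuzzifier weight exponent p (> 1).
#' @param lambda_spatial weight of the mask-indicator feature.
#' @param tol,max_iter,seed,init passed to [fcm_fit()].
#' @return an `rgsc_fcm` object; `U` rows are in column-major pixel order.
#' @export
rg_fcm <- function(img, rg, clusters = 2L, fuzzifier = 2, lambda_spatial = 128,
                   tol = 1e-5, max_iter = 200L, seed = 0L, init = NULL) {
  img <- as_gray_image(img)
  stopifnot(inherits(rg, "rgsc_region"))
  check_same_dim(img, rg$mask)
  x <- cbind(as.numeric(img), lambda_spatial * as.numeric(rg$mask))
  fcm_fit(x, m = clusters, p = fuzzifier, tol = tol, max_iter = max_iter,
          seed = seed, init = init)
}

#' Extract the ROI mask from an RG-FCM state
#'
#' Each pixel is assigned to its maximum-membership cluster (ties to the
#' lowest cluster index); the ROI cluster is the one whose pixel set overlaps
#' the region-growing mask the most (ties to the higher-intensity centroid).
#' The resulting mask is cleaned up by filling holes and keeping only the
#' largest 8-connected component.
#'
#' @param fcm `rgsc_fcm` computed on `img` with `rg` (see [rg_fcm()]).
#' @param img the image the clustering was run on.
#' @param rg the `rgsc_region` used for the spatial constraint.
#' @return logical ROI mask with the image's dimensions.
#' @export
extract_roi <- function(fcm, img, rg) {
  img <- as_gray_image(img)
  stopifnot(inherits(fcm, "rgsc_fcm"), inherits(rg, "rgsc_region"))
  if (nrow(fcm$U) != length(img)) {
    rgsc_error("rgsc_dim_mismatch", "FCM state does not match the image size")
  }
  assign <- max.col(fcm$U, ties.method = "first")
  inside <- as.integer(rg$mask)
  overlap <- vapply(seq_len(fcm$m),
                    function(i) sum(inside[assign == i]), numeric(1))
  best <- which(overlap == max(overlap))
  if (length(best) > 1L) {
    best <- best[which.max(fcm$V[best, 1L])]   # higher intensity centroid
  }
  mask <- matrix(assign == best, nrow(img), ncol(img))
  if (!any(mask)) return(mask)
  filled <- EBImage::imageData(
    EBImage::fillHull(matrix(as.integer(mask), nrow(img), ncol(img))))
  lab <- EBImage::imageData(EBImage::bwlabel(filled))
  sizes <- tabulate(lab[lab > 0])
  matrix(lab == which.max(sizes), nrow(img), ncol(img))
}

#' Segmentation configuration
#'
#' @param clusters FCM cluster count.
#' @param fuzzifier FCM weight exponent p.
#' @param lambda_spatial weight of the region-growing indicator feature.
#' @param rg_tol_factor region-growing tolerance as a fraction of the Otsu
#'   between-class contrast `|mean(fg) - mean(bg)|`.
#' @param fcm_tol FCM convergence tolerance.
#' @param max_iter FCM iteration cap.
#' @param seed RNG seed for FCM initialization.
#' @return a list of class `rgsc_seg_config`.
#' @export
seg_config <- function(clusters = 2L, fuzzifier = 2, lambda_spatial = 128,
                       rg_tol_factor = 0.15, fcm_tol = 1e-5, max_iter = 200L,
                       seed = 0L) {
  structure(list(clusters = as.integer(clusters), fuzzifier = fuzzifier,
                 lambda_spatial = lambda_spatial,
                 rg_tol_factor = rg_tol_factor, fcm_tol = fcm_tol,
                 max_iter = as.integer(max_iter), seed = as.integer(seed)),
            class = "rgsc_seg_config")
}

#' Full RG-FCM segmentation of a grayscale image
#'
#' Composition of the whole segmentation chain: Otsu threshold, seed
#' selection at the foreground mean, region growing with tolerance
#' `rg_tol_factor * |mean(fg) - mean(bg)|`, RG-FCM clustering and ROI
#' extraction with morphological cleanup.  Deterministic for a fixed
#' `config$seed`.
#'
#' @param img integer matrix in \[0, 255\], at least 16x16.
#' @param config a [seg_config()].
#' @return object of class `rgsc_segmentation`: `roi_mask`, `fcm`, `rg`,
#'   `otsu_threshold`, `seed`, `config`.
#' @export
segment_roi <- function(img, config = seg_config()) {
  img <- as_gray_image(img, min_dim = 16L)
  t <- otsu_threshold(img)
  seed <- select_seed(img, t)
  fg <- img > t
  tol <- config$rg_tol_factor * abs(mean(img[fg]) - mean(img[!fg]))
  rg <- region_grow(img, seed, tol)
  fcm <- rg_fcm(img, rg,
                clusters = config$clusters, fuzzifier = config$fuzzifier,
                lambda_spatial = config$lambda_spatial, tol = config$fcm_tol,
                max_iter = config$max_iter, seed = config$seed)
  roi <- extract_roi(fcm, img, rg)
  structure(list(roi_mask = roi, fcm = fcm, rg = rg,
                 otsu_threshold = t, seed = seed, config = config),
            class = "rgsc_segmentation")
}

#' @export
print.rgsc_segmentation <- function(x, ...) {
  cat(sprintf(
    "RG-FCM segmentation: otsu=%d seed=(%d,%d) rg tol=%.2f roi=%.2f%% of frame\n",
    x$otsu_threshold, x$seed[1L], x$seed[2L], x$rg$tolerance,
    100 * mean(x$roi_mask)))
  invisible(x)
}

#' @export
print.rgsc_fcm <- function(x, ...) {
  cat(sprintf("FCM state: m=%d p=%.2f iterations=%d converged=%s objective=%.4g\n",
              x$m, x$p, x$iterations, x$converged,
              tail(x$objective_trace, 1L)))
  invisible(x)
}
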