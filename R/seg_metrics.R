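#' Jaccard index of two binary masks
#'
#' `|R intersect G| / |R union G|`.  Two empty masks agree perfectly, so the
#' index is defined as 1 in that case.
#'
#' @param r,g logical matrices of identical dimensions.
#' @return ratio in \[0, 1\].
#' @export
jaccard_index <- function(r, g) {
  r <- as_binary_mask(r); g <- as_binary_mask(g)
  check_same_dim(r, g)
  u <- sum(r | g)
  if (u == 0L) return(1)
  sum(r & g) / u
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|R intersect G| / (|R| + |G|)`; 1 when both masks are empty.
#'
#' @inheritParams jaccard_index
#' @return ratio in \[0, 1\].
#' @export
dice_index <- function(r, g) {
  r <- as_binary_mask(r); g <- as_binary_mask(g)
  check_same_dim(r, g)
  s <- sum(r) + sum(g)
  if (s == 0L) return(1)
  2 * sum(r & g) / s
}

#' Percentage of foreground area of a mask
#'
#' @param mask logical matrix.
#' @return `100 * foreground pixels / total pixels`.
#' @export
foreground_area_pct <- function(mask) {
  mask <- as_binary_mask(mask)
  100 * sum(mask) / length(mask)
}

#' Precision, recall and F-measure of a predicted mask
#'
#' Pixel-wise confusion counts against the ground truth `g`:
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, `F = 2PR/(P+R)`; any 0/0
#' is reported as 0.  With `boundary = TRUE` the counts are restricted to
#' mask boundaries: a boundary pixel of one mask matches if it lies within a
#' Chebyshev distance `band` of the other mask's boundary.
#'
#' @param r predicted mask; @param g ground-truth mask.
#' @param boundary use the boundary-band variant instead of pixel-wise.
#' @param band tolerance in pixels for the boundary variant.
#' @return named numeric vector `c(precision, recall, f_measure)`.
#' @export
precision_recall_f <- function(r, g, boundary = FALSE, band = 2L) {
  r <- as_binary_mask(r); g <- as_binary_mask(g)
  check_same_dim(r, g)
  if (boundary) {
    rb <- mask_boundary(r); gb <- mask_boundary(g)
    gd <- dilate_mask(gb, band); rd <- dilate_mask(rb, band)
    p <- safe_div(sum(rb & gd), sum(rb))
    rec <- safe_div(sum(gb & rd), sum(gb))
  } else {
    tp <- sum(r & g)
    p <- safe_div(tp, sum(r))
    rec <- safe_div(tp, sum(g))
  }
  f <- if (p + rec > 0) 2 * p * rec / (p + rec) else 0
  c(precision = p, recall = rec, f_measure = f)
}

safe_div <- function(num, den) if (den > 0) num / den else 0

# Boundary = foreground pixels with at least one 4-neighbour outside the mask
# (image border counts as outside).
mask_boundary <- function(m) {
  H <- nrow(m); W <- ncol(m)
  up <- rbind(FALSE, m[-H, , drop = FALSE])
  dn <- rbind(m[-1L, , drop = FALSE], FALSE)
  lf <- cbind(FALSE, m[, -W, drop = FALSE])
  rt <- cbind(m[, -1L, drop = FALSE], FALSE)
  m & !(up & dn & lf & rt)
}

dilate_mask <- function(m, band) {
  if (band <= 0L || !any(m)) return(m)
  k <- EBImage::makeBrush(2L * as.integer(band) + 1L, shape = "box")
  EBImage::imageData(EBImage::dilate(matrix(as.integer(m), nrow(m), ncol(m)), k)) > 0
}

#' Normal-approximation confidence interval for a sample mean
#'
#' `mean -/+ z * sd / sqrt(n)` with the conventional rounded critical values
#' z = 1.65, 1.96 and 2.58 at the 90%, 95% and 99% levels.
#'
#' @param mean sample mean of the statistic.
#' @param sd sample standard deviation.
#' @param n sample count (>= 2).
#' @param level one of 90, 95, 99.
#' @return object of class `rgsc_ci` with `lower`, `upper`, `level`, `z`, `n`.
#' @export
confidence_interval <- function(mean, sd, n, level = 95) {
  zs <- c(`90` = 1.65, `95` = 1.96, `99` = 2.58)
  key <- as.character(level)
  if (!key %in% names(zs)) {
    rgsc_error("rgsc_unsupported_level", "level must be one of 90, 95, 99")
  }
  if (n < 2) rgsc_error("rgsc_bad_argument", "n must be >= 2")
  if (sd < 0) rgsc_error("rgsc_bad_argument", "sd must be >= 0")
  z <- zs[[key]]
  half <- z * sd / sqrt(n)
  structure(list(level = level, z = z, n = n,
                 lower = mean - half, upper = mean + half),
            class = "rgsc_ci")
}

#' @export
print.rgsc_ci <- function(x, ...) {
  cat(sprintf("%d%% CI (z=%.2f, n=%d): %.4f-%.4f\n",
              x$level, x$z, x$n, x$lower, x$upper))
  invisible(x)
}

#' All segmentation scores of a predicted mask against ground truth
#'
#' @param pred predicted logical mask.
#' @param truth ground-truth logical mask.
#' @param boundary,band passed to [precision_recall_f()].
#' @return named list: jaccard, dice, area_pct, precision, recall, f_measure.
#' @export
evaluate_segmentation <- function(pred, truth, boundary = FALSE, band = 2L) {
  prf <- precision_recall_f(pred, truth, boundary = boundary, band = band)
  list(jaccard = jaccard_index(pred, truth),
       dice = dice_index(pred, truth),
       area_pct = foreground_area_pct(pred),
       precision = unname(prf["precision"]),
       recall = unname(prf["recall"]),
       f_measure = unname(prf["f_measure"]))
}
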