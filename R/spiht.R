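#' Top bitplane of an integer coefficient plane
#'
#' `floor(log2(max |C|))`; -1 for an all-zero plane (the encoder then emits
#' an empty payload and only header information is stored).
#'
#' @param plane an `rgsc_plane` from [quantize_coeffs()].
#' @return integer bitplane index `b_max`.
#' @export
spiht_max_bitplane <- function(plane) {
  stopifnot(inherits(plane, "rgsc_plane"))
  peak <- max(plane$mag)
  if (peak == 0L) return(-1L)
  as.integer(floor(log2(peak)))
}

#' Significance of a coordinate set at a bitplane
#'
#' 1 iff the maximum magnitude over the coordinates reaches `2^n`; an empty
#' set is insignificant.
#'
#' @param coords integer matrix with one (row, col) pair per row, 1-based.
#' @param n bitplane index (>= 0).
#' @param plane an `rgsc_plane`.
#' @return 0 or 1.
#' @export
spiht_significant <- function(coords, n, plane) {
  stopifnot(inherits(plane, "rgsc_plane"), n >= 0)
  if (is.null(coords) || NROW(coords) == 0L) return(0L)
  coords <- matrix(as.integer(coords), ncol = 2L)
  as.integer(max(plane$mag[coords]) >= 2^n)
}

#' Offspring of a coordinate in the spatial-orientation tree
#'
#' Outside the coarsest approximation band, coordinate (i, j) has offspring
#' (2i-1..2i, 2j-1..2j) in 1-based terms when in bounds.  Inside the
#' coarsest LL, the top-left member of each 2x2 group is rootless and the
#' other three members parent the co-located 2x2 blocks of the coarsest
#' HL/LH/HH bands.
#'
#' @param row,col 1-based coordinate.
#' @param dim plane dimensions `c(H, W)` (padded, divisible by
#'   `2^(levels+1)`).
#' @param levels decomposition level count.
#' @return integer matrix of 1-based offspring coordinates (0 or 4 rows).
#' @export
spiht_offspring <- function(row, col, dim, levels) {
  out <- .spiht_offspring_cpp(as.integer(row) - 1L, as.integer(col) - 1L,
                              as.integer(dim[1L]), as.integer(dim[2L]),
                              as.integer(levels))
  out + 1L
}

#' SPIHT-encode an integer coefficient plane
#'
#' Embedded bitplane coding with the Said-Pearlman list dynamics (LIP, LIS,
#' LSP; sorting and refinement passes from bitplane `b_max` down to 0).  The
#' output stream is truncated exactly at `budget_bits`, mid-pass if needed,
#' so the emitted length is `min(bits needed to reach plane 0, budget)`.
#'
#' @param plane an `rgsc_plane`.
#' @param budget_bits maximum stream length in bits (`Inf` = unlimited).
#' @return object of class `rgsc_bitstream`: `bits` (raw 0x00/0x01 vector),
#'   `b_max`, `nbits`, plus the plane geometry needed for decoding.
#' @export
spiht_encode <- function(plane, budget_bits = Inf) {
  stopifnot(inherits(plane, "rgsc_plane"))
  if (budget_bits < 0) rgsc_error("rgsc_bad_argument", "budget must be >= 0")
  b <- if (is.finite(budget_bits)) as.numeric(floor(budget_bits)) else -1
  res <- .spiht_encode_cpp(plane$mag, plane$sign, plane$levels, b)
  structure(list(bits = res$bits, b_max = res$b_max, nbits = res$nbits,
                 dim = dim(plane$mag), levels = plane$levels),
            class = "rgsc_bitstream")
}

#' SPIHT-decode a bit sequence
#'
#' Mirrors the encoder's list dynamics while consuming bits.  A coefficient
#' that becomes significant at plane n is reconstructed at +/- 1.5 * 2^n and
#' each refinement bit halves its uncertainty interval; when the stream ends
#' mid-pass decoding stops gracefully with the remaining coefficients at 0.
#' A complete stream (down to plane 0) yields exact integer recovery.
#'
#' @param bits raw vector of 0x00/0x01 bit values, or an `rgsc_bitstream`.
#' @param dim plane dimensions `c(H, W)`; ignored for an `rgsc_bitstream`.
#' @param levels decomposition level count.
#' @param b_max top bitplane recorded by the encoder.
#' @return numeric matrix of reconstructed coefficient values.
#' @export
spiht_decode <- function(bits, dim = NULL, levels = NULL, b_max = NULL) {
  if (inherits(bits, "rgsc_bitstream")) {
    dim <- bits$dim; levels <- bits$levels; b_max <- bits$b_max
    bits <- bits$bits
  }
  if (is.null(dim) || is.null(levels) || is.null(b_max)) {
    rgsc_error("rgsc_malformed_stream", "decode needs dim, levels and b_max")
  }
  ok <- tryCatch({
    .spiht_decode_cpp(as.raw(bits), as.integer(dim[1L]), as.integer(dim[2L]),
                      as.integer(levels), as.integer(b_max))
  }, error = function(e) {
    rgsc_error("rgsc_malformed_stream", conditionMessage(e))
  })
  ok
}

#' @export
print.rgsc_bitstream <- function(x, ...) {
  cat(sprintf("SPIHT stream: %d bits, b_max=%d, %dx%d plane, %d levels\n",
              as.integer(x$nbits), x$b_max, x$dim[1L], x$dim[2L], x$levels))
  invisible(x)
}
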