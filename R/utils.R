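# Classed error conditions used across the package.  Every domain error is an
# "rgsc_error"; tests and callers dispatch on the specific class.
rgsc_error <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "rgsc_error", "error", "condition")))
}

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the caller's
#' RNG state afterwards so seeded internals never disturb user simulations.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# Validate an 8-bit grayscale image matrix; returns it as an integer matrix.
as_gray_image <- function(img, min_dim = 1L) {
  if (!is.matrix(img) || !is.numeric(img)) {
    rgsc_error("rgsc_bad_image", "image must be a numeric matrix")
  }
  if (nrow(img) < min_dim || ncol(img) < min_dim) {
    rgsc_error("rgsc_image_too_small",
               sprintf("image must be at least %dx%d", min_dim, min_dim))
  }
  if (anyNA(img) || any(img < 0) || any(img > 255)) {
    rgsc_error("rgsc_bad_image", "pixel values must lie in [0, 255]")
  }
  storage.mode(img) <- "integer"
  img
}

as_binary_mask <- function(mask, ref = NULL) {
  if (!is.matrix(mask)) rgsc_error("rgsc_bad_mask", "mask must be a matrix")
  if (!is.logical(mask)) {
    mask <- matrix(as.numeric(mask) != 0, nrow(mask), ncol(mask))
  }
  if (!is.null(ref) && !identical(dim(mask), dim(ref))) {
    rgsc_error("rgsc_dim_mismatch", "mask dimensions do not match the image")
  }
  mask
}

check_same_dim <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    rgsc_error("rgsc_dim_mismatch", "inputs must have identical dimensions")
  }
  invisible(TRUE)
}

# Row-major linear index (1-based) of matrix coordinates; the tie-breaking
# order used wherever the API promises "smallest row-major index".
row_major_index <- function(row, col, ncol) (row - 1L) * ncol + col

#' Pack a bit vector into bytes, most significant bit first
#'
#' @param bits raw or integer vector of 0/1 values.
#' @return raw vector; the final byte is zero-padded.
#' @keywords internal
pack_bits_msb <- function(bits) {
  n <- length(bits)
  if (n == 0L) return(raw(0))
  b <- as.integer(bits)
  pad <- (8L - n %% 8L) %% 8L
  if (pad > 0L) b <- c(b, integer(pad))
  m <- matrix(b, nrow = 8L)
  as.raw(as.integer(colSums(m * c(128L, 64L, 32L, 16L, 8L, 4L, 2L, 1L))))
}

#' Unpack bytes into a bit vector, most significant bit first
#'
#' @param bytes raw vector.
#' @param nbits number of leading bits that are meaningful.
#' @return raw vector of 0x00/0x01 values of length `nbits`.
#' @keywords internal
unpack_bits_msb <- function(bytes, nbits = 8L * length(bytes)) {
  if (nbits == 0L) return(raw(0))
  if (nbits > 8L * length(bytes)) {
    rgsc_error("rgsc_malformed_packet", "bit count exceeds available bytes")
  }
  m <- matrix(rawToBits(bytes), nrow = 8L)  # LSB-first within each byte
  bits <- as.raw(m[8:1, , drop = FALSE])
  bits[seq_len(nbits)]
}

# Big-endian binary writers/readers over raw connections.
write_u8  <- function(con, x) writeBin(as.integer(x), con, size = 1L, endian = "big")
write_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2L, endian = "big")
write_u32 <- function(con, x) writeBin(as.integer(x), con, size = 4L, endian = "big")
write_f32 <- function(con, x) writeBin(as.numeric(x), con, size = 4L, endian = "big")

read_u8 <- function(raw, at) as.integer(raw[at])
read_u16 <- function(raw, at) {
  v <- as.integer(raw[at:(at + 1L)])
  v[1L] * 256L + v[2L]
}
read_u32 <- function(raw, at) {
  v <- as.numeric(as.integer(raw[at:(at + 3L)]))
  v[1L] * 16777216 + v[2L] * 65536 + v[3L] * 256 + v[4L]
}
read_f32 <- function(raw, at) {
  readBin(raw[at:(at + 3L)], "numeric", n = 1L, size = 4L, endian = "big")
}
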