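#' Read an 8-bit grayscale image
#'
#' Reads PNG or PGM (P2/P5) files into an integer matrix with values in
#' \[0, 255\]. Color PNGs are converted to luma with the ITU-R BT.601 weights
#' (0.299, 0.587, 0.114) and rounded.
#'
#' @param path file path; format chosen by extension (`.png`, `.pgm`).
#' @return integer matrix (rows x cols) in \[0, 255\].
#' @export
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(read_pgm(path))
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) {
    nc <- dim(x)[3L]
    if (nc >= 3L) {
      x <- 0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L]
    } else {
      x <- x[, , 1L]
    }
  }
  img <- round(x * 255)
  storage.mode(img) <- "integer"
  img
}

#' Write an 8-bit grayscale image
#'
#' @param img integer matrix in \[0, 255\].
#' @param path destination; `.png` or `.pgm` by extension.
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path) {
  img <- as_gray_image(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    write_pgm(img, path)
  } else {
    png::writePNG(img / 255, path)
  }
  invisible(path)
}

#' Read a binary mask image
#'
#' Any pixel above 127 counts as foreground.
#'
#' @param path PNG or PGM file.
#' @return logical matrix.
#' @export
read_mask <- function(path) read_gray(path) > 127L

#' Write a binary mask as a 0/255 image
#'
#' @param mask logical matrix.
#' @param path destination PNG/PGM path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- as_binary_mask(mask)
  write_gray(matrix(ifelse(mask, 255L, 0L), nrow(mask), ncol(mask)), path)
}

# Minimal PGM support (maxval <= 255). P5 is raw, P2 is ASCII.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) rgsc_error("rgsc_malformed_packet", "truncated PGM")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
      } else if (!grepl("[ \t\r\n]", ch)) {
        out <- ch
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || grepl("[ \t\r\n]", ch)) break
          out <- paste0(out, ch)
        }
        return(out)
      }
    }
  }
  magic <- tok()
  if (!magic %in% c("P2", "P5")) {
    rgsc_error("rgsc_malformed_packet", "not a PGM file")
  }
  w <- as.integer(tok()); h <- as.integer(tok()); maxv <- as.integer(tok())
  if (maxv > 255L) rgsc_error("rgsc_malformed_packet", "only 8-bit PGM supported")
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n = w * h))
  } else {
    scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  if (length(vals) < w * h) rgsc_error("rgsc_malformed_packet", "truncated PGM")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(img, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(img), nrow(img)), con, eos = NULL)
  writeBin(as.raw(as.integer(t(img))), con)
  invisible(path)
}
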