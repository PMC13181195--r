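#' Build a canonical Huffman table from byte frequencies
#'
#' Standard Huffman merging with deterministic tie-breaking: nodes are
#' ordered by count, then leaves by symbol value (leaves before internal
#' nodes at equal count), then internal nodes by creation order.  The
#' resulting code lengths are converted to canonical codes (shorter codes
#' first, ties by symbol value), so only lengths need to be stored.
#'
#' A single-symbol alphabet receives the degenerate length-1 code.
#'
#' @param freqs integer vector of length 256 with counts for byte values
#'   0..255 (or a named vector of counts whose names are byte values).
#' @return object of class `rgsc_huffman_table`: data.frame `entries` with
#'   `symbol` (0-based byte value), `length`, `code` (integer code value),
#'   in canonical order.
#' @export
huffman_table <- function(freqs) {
  if (!is.null(names(freqs))) {
    f <- integer(256)
    f[as.integer(names(freqs)) + 1L] <- as.integer(freqs)
    freqs <- f
  }
  stopifnot(length(freqs) == 256L)
  syms <- which(freqs > 0L) - 1L          # 0-based byte values
  if (length(syms) == 0L) {
    rgsc_error("rgsc_empty_input", "no symbol has a positive count")
  }
  if (length(syms) == 1L) {
    lens <- 1L
  } else {
    # node fields: count, tie key (symbol for leaves, 256+creation for
    # internal), left child, right child, depth accumulator via parents
    n_leaf <- length(syms)
    count <- as.numeric(freqs[syms + 1L])
    tie <- as.numeric(syms)
    parent <- integer(2L * n_leaf - 1L)
    alive <- rep(TRUE, n_leaf)
    created <- 0L
    while (sum(alive) > 1L) {
      idx <- which(alive)
      ord <- idx[order(count[idx], tie[idx])]
      a <- ord[1L]; b <- ord[2L]
      created <- created + 1L
      new <- length(count) + 1L
      count <- c(count, count[a] + count[b])
      tie <- c(tie, 256 + created)
      alive <- c(alive, TRUE)
      alive[c(a, b)] <- FALSE
      parent[c(a, b)] <- new
      parent <- c(parent[seq_len(new - 1L)], 0L)
    }
    # depth of each leaf = number of parent hops to the root
    lens <- vapply(seq_len(n_leaf), function(i) {
      d <- 0L
      while (parent[i] != 0L) {
        i <- parent[i]
        d <- d + 1L
      }
      d
    }, integer(1))
  }
  ord <- order(lens, syms)
  symbol <- syms[ord]
  length_ <- lens[ord]
  code <- integer(length(symbol))
  cur <- 0
  prev_len <- length_[1L]
  for (i in seq_along(symbol)) {
    if (length_[i] > prev_len) {
      cur <- cur * 2^(length_[i] - prev_len)
      prev_len <- length_[i]
    }
    code[i] <- cur
    cur <- cur + 1
  }
  structure(list(entries = data.frame(symbol = symbol, length = length_,
                                      code = code)),
            class = "rgsc_huffman_table")
}

# Integer code value -> 0/1 bit vector of given length.
code_bits <- function(code, len) {
  as.integer(rev((floor(code / 2^(seq_len(len) - 1)) %% 2)))
}

#' Huffman-encode a byte sequence into a self-describing packet
#'
#' Packet layout (big-endian): u16 symbol count; per symbol u8 value and u8
#' canonical code length; u32 payload bit count; payload bits MSB-first,
#' zero-padded to a byte boundary.  Empty input produces a header-only
#' packet.
#'
#' @param data raw vector.
#' @return raw vector, the serialized packet (class `rgsc_huffman_packet`).
#' @export
huffman_encode <- function(data) {
  data <- as.raw(data)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  if (length(data) == 0L) {
    write_u16(con, 0L)
    write_u32(con, 0L)
    out <- rawConnectionValue(con)
    class(out) <- c("rgsc_huffman_packet", class(out))
    return(out)
  }
  freqs <- tabulate(as.integer(data) + 1L, nbins = 256L)
  tab <- huffman_table(freqs)
  e <- tab$entries
  write_u16(con, nrow(e))
  for (i in seq_len(nrow(e))) {
    write_u8(con, e$symbol[i])
    write_u8(con, e$length[i])
  }
  # per-symbol bit patterns, then one lookup per input byte
  codes <- vector("list", 256L)
  for (i in seq_len(nrow(e))) {
    codes[[e$symbol[i] + 1L]] <- code_bits(e$code[i], e$length[i])
  }
  payload <- unlist(codes[as.integer(data) + 1L], use.names = FALSE)
  write_u32(con, length(payload))
  writeBin(pack_bits_msb(payload), con)
  out <- rawConnectionValue(con)
  class(out) <- c("rgsc_huffman_packet", class(out))
  out
}

#' Decode a Huffman packet back to the original bytes
#'
#' Validates the table (Kraft inequality, payload length) and raises a
#' malformed-packet error on any inconsistency.
#'
#' @param packet raw vector produced by [huffman_encode()].
#' @return raw vector of the original bytes.
#' @export
huffman_decode <- function(packet) {
  packet <- as.raw(packet)
  if (length(packet) < 6L) {
    rgsc_error("rgsc_malformed_packet", "packet shorter than its header")
  }
  nsym <- read_u16(packet, 1L)
  at <- 3L
  if (nsym == 0L) {
    nbits <- read_u32(packet, at)
    if (nbits != 0) rgsc_error("rgsc_malformed_packet", "payload without table")
    return(raw(0))
  }
  if (length(packet) < at + 2L * nsym + 3L) {
    rgsc_error("rgsc_malformed_packet", "truncated symbol table")
  }
  symbol <- integer(nsym)
  len <- integer(nsym)
  for (i in seq_len(nsym)) {
    symbol[i] <- read_u8(packet, at)
    len[i] <- read_u8(packet, at + 1L)
    at <- at + 2L
  }
  if (any(len < 1L)) rgsc_error("rgsc_malformed_packet", "zero code length")
  if (nsym > 1L && sum(2^(-len)) > 1 + 1e-12) {
    rgsc_error("rgsc_malformed_packet", "code lengths violate the Kraft bound")
  }
  nbits <- read_u32(packet, at)
  at <- at + 4L
  avail <- 8 * (length(packet) - at + 1L)
  if (nbits > avail) {
    rgsc_error("rgsc_malformed_packet", "truncated payload")
  }
  bits <- as.integer(unpack_bits_msb(packet[at:length(packet)], nbits))

  # canonical decode: first code value and first table index per length
  ord <- order(len, symbol)
  symbol <- symbol[ord]; len <- len[ord]
  code <- integer(nsym)
  cur <- 0; prev <- len[1L]
  for (i in seq_len(nsym)) {
    if (len[i] > prev) {
      cur <- cur * 2^(len[i] - prev)
      prev <- len[i]
    }
    code[i] <- cur
    cur <- cur + 1
  }
  maxlen <- max(len)
  first_code <- rep(NA_real_, maxlen)
  first_idx <- rep(NA_integer_, maxlen)
  count_len <- tabulate(len, nbins = maxlen)
  for (L in seq_len(maxlen)) {
    if (count_len[L] > 0L) {
      i <- which(len == L)[1L]
      first_code[L] <- code[i]
      first_idx[L] <- i
    }
  }
  out <- raw(0)
  res <- integer(0)
  val <- 0; L <- 0L; pos <- 1L
  n <- length(bits)
  res <- integer(ceiling(n))  # upper bound: one symbol per bit
  nout <- 0L
  while (pos <= n) {
    val <- val * 2 + bits[pos]
    L <- L + 1L
    pos <- pos + 1L
    if (L <= maxlen && !is.na(first_code[L]) &&
        val - first_code[L] < count_len[L] && val >= first_code[L]) {
      nout <- nout + 1L
      res[nout] <- symbol[first_idx[L] + (val - first_code[L])]
      val <- 0; L <- 0L
    } else if (L >= maxlen) {
      rgsc_error("rgsc_malformed_packet", "undecodable bit pattern")
    }
  }
  if (L != 0L) rgsc_error("rgsc_malformed_packet", "payload ends mid-symbol")
  as.raw(res[seq_len(nout)])
}
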