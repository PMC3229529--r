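# Low-level serialization primitives: MSB-first bitstreams, LEB128 varints,
# zigzag folding, CRC-32. All integer values travel as doubles and must stay
# below 2^53 so that arithmetic is exact.

MAX_SAFE_INT <- 2^53

#' Pack a 0/1 bit vector into bytes, most-significant bit first
#'
#' The final partial byte, if any, is zero-padded on the right.
#'
#' @param bits integer vector of 0s and 1s.
#' @return A bitstream: list with `bytes` (raw vector) and `bit_count`.
#' @export
bits_to_raw <- function(bits) {
  n <- length(bits)
  if (n == 0L) return(list(bytes = raw(0), bit_count = 0L))
  pad <- (8L - n %% 8L) %% 8L
  if (pad > 0L) bits <- c(bits, integer(pad))
  m <- matrix(as.integer(bits), nrow = 8L)
  # packBits() treats the first element as the least-significant bit
  list(bytes = packBits(as.vector(m[8:1, , drop = FALSE]), type = "raw"),
       bit_count = n)
}

#' Unpack bytes into a 0/1 bit vector, most-significant bit first
#'
#' @param bytes raw vector.
#' @param nbits number of bits to return (trailing padding is dropped).
#' @return Integer vector of 0s and 1s, length `nbits`.
#' @export
raw_to_bits <- function(bytes, nbits) {
  nbits <- as.integer(nbits)
  if (nbits == 0L) return(integer(0))
  if (nbits > 8L * length(bytes))
    stop_corrupt("bitstream shorter than requested bit count")
  b <- as.integer(rawToBits(bytes))
  m <- matrix(b, nrow = 8L)
  as.vector(m[8:1, , drop = FALSE])[seq_len(nbits)]
}

#' Encode non-negative integers as LEB128 varints
#'
#' Little-endian base-128 with a continuation bit in the MSB of each byte.
#' Vectorized: the encodings of all elements are concatenated in order.
#'
#' @param x numeric vector of non-negative integers (each below 2^53).
#' @return Raw vector.
#' @export
varint_encode <- function(x) {
  x <- as.double(x)
  n <- length(x)
  if (n == 0L) return(raw(0))
  if (anyNA(x) || any(x < 0) || any(x >= MAX_SAFE_INT) || any(x != floor(x)))
    stop("varint_encode requires non-negative integers below 2^53")
  # number of base-128 digits per value
  ndig <- rep(1, n)
  for (k in 1:7) ndig <- ndig + (x >= 128^k)
  idx <- rep(seq_len(n), ndig)
  layer <- sequence(ndig)
  digit <- (x[idx] %/% 128^(layer - 1)) %% 128
  byte <- digit + ifelse(layer < ndig[idx], 128, 0)
  as.raw(byte)
}

#' Decode LEB128 varints
#'
#' @param bytes raw vector containing the stream.
#' @param n number of varints to read.
#' @param offset 1-based position of the first byte to read.
#' @return List with `values` (numeric vector of length `n`) and `offset`
#'   (position of the first unread byte).
#' @export
varint_decode <- function(bytes, n, offset = 1L) {
  n <- as.integer(n)
  if (n == 0L) return(list(values = numeric(0), offset = offset))
  if (offset > length(bytes)) stop_corrupt("truncated varint stream")
  b <- as.integer(bytes[offset:length(bytes)])
  cont <- b >= 128L
  ends <- which(!cont)
  if (length(ends) < n) stop_corrupt("truncated varint stream")
  last <- ends[n]
  b <- b[seq_len(last)]
  grp <- cumsum(c(TRUE, !cont[seq_len(last - 1L)]))
  lens <- tabulate(grp, nbins = n)
  if (any(lens > 8L)) stop_corrupt("varint wider than 8 bytes")
  pos <- sequence(lens) - 1
  vals <- rowsum((b %% 128L) * 128^pos, grp, reorder = FALSE)
  list(values = as.vector(vals), offset = offset + last)
}

#' Zigzag-fold signed integers onto the non-negative integers
#'
#' 0 -> 0, -1 -> 1, 1 -> 2, -2 -> 3, ... A bijection, so signed deltas can be
#' stored as varints.
#'
#' @param i numeric vector of integers (|i| below 2^52).
#' @return Non-negative numeric vector.
#' @export
zigzag <- function(i) {
  i <- as.double(i)
  ifelse(i >= 0, 2 * i, -2 * i - 1)
}

#' Invert the zigzag fold
#'
#' @param z non-negative numeric vector.
#' @return Signed numeric vector.
#' @export
unzigzag <- function(z) {
  z <- as.double(z)
  ifelse(z %% 2 == 0, z / 2, -(z + 1) / 2)
}

#' CRC-32 checksum of a raw vector
#'
#' IEEE 802.3 polynomial, as used by gzip; returned as 4 little-endian bytes.
#'
#' @param bytes raw vector.
#' @return Raw vector of length 4.
#' @export
crc32 <- function(bytes) {
  stopifnot(is.raw(bytes))
  .Call(samzip_crc32, bytes)
}

# Condition helpers -----------------------------------------------------------

stop_corrupt <- function(msg, class = "samzip_corrupt") {
  stop(structure(class = c(class, "samzip_corrupt", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_malformed <- function(msg) {
  stop(structure(class = c("samzip_malformed", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
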