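# Reusable codec primitives: run-length encoding over arbitrary tokens,
# delta encoding of integer sequences, canonical Huffman coding, and 2-bit
# packing of ACGT sequence.

#' Run-length encode a token sequence
#'
#' A run of identical adjacent values is stored once together with its count.
#'
#' @param tokens atomic vector (typically character).
#' @return List with `values` and `counts` (integer); adjacent values are
#'   guaranteed distinct and `sum(counts) == length(tokens)`.
#' @export
rle_encode <- function(tokens) {
  if (length(tokens) == 0L) return(list(values = tokens, counts = integer(0)))
  r <- rle(tokens)
  list(values = r$values, counts = r$lengths)
}

#' Expand a run-length encoding
#'
#' @param runs list with `values` and `counts`, as from [rle_encode()].
#' @return The original token sequence.
#' @export
rle_decode <- function(runs) {
  counts <- runs$counts
  if (length(counts) != length(runs$values))
    stop_corrupt("run values and counts differ in length")
  if (any(counts <= 0))
    stop_corrupt("non-positive run count")
  rep(runs$values, counts)
}

#' Delta encode an integer sequence
#'
#' Stores the first value and successive differences; differences may be
#' negative.
#'
#' @param values numeric vector of integers.
#' @return List with `first` (NULL for empty input) and `diffs`.
#' @export
delta_encode <- function(values) {
  values <- as.double(values)
  if (length(values) == 0L) return(list(first = NULL, diffs = numeric(0)))
  list(first = values[1L], diffs = diff(values))
}

#' Invert delta encoding by prefix summation
#'
#' @param first first value (or NULL for the empty sequence).
#' @param diffs numeric vector of successive differences.
#' @return The original value sequence.
#' @export
delta_decode <- function(first, diffs) {
  if (is.null(first)) {
    if (length(diffs) > 0L) stop_corrupt("delta stream with diffs but no first value")
    return(numeric(0))
  }
  cumsum(c(as.double(first), as.double(diffs)))
}

# Canonical Huffman -----------------------------------------------------------

#' Build a canonical Huffman code table from symbol frequencies
#'
#' Code lengths are obtained by the classical two-least-frequent merge; ties
#' are broken deterministically by (weight, creation order). Codes are then
#' assigned canonically -- symbols sorted by (length, symbol byte order),
#' consecutive codes within a length -- so the table can be reconstructed from
#' the lengths alone. A single-symbol alphabet is assigned a 1-bit code.
#'
#' @param freqs named numeric vector (or table) of positive symbol counts.
#' @return A code table: list with `symbols`, `lengths` and `codes` (bit
#'   strings), in canonical order.
#' @export
huffman_build <- function(freqs) {
  freqs <- unlist(as.list(freqs))
  if (length(freqs) == 0L) stop("huffman_build requires at least one symbol")
  if (is.null(names(freqs)) || any(!is.finite(freqs)) || any(freqs <= 0))
    stop("huffman_build requires named positive counts")
  syms <- names(freqs)
  if (anyDuplicated(syms)) stop("duplicate symbols in frequency table")
  k <- length(syms)
  depth <- stats::setNames(integer(k), syms)
  if (k == 1L) {
    depth[1L] <- 1L
  } else {
    # stable seeding: process symbols in byte order so equal-weight merges
    # are reproducible
    o <- order(as.double(freqs), syms, method = "radix")
    nodes <- lapply(o, function(i) list(w = as.double(freqs[[i]]), leaves = syms[i]))
    while (length(nodes) > 1L) {
      ws <- vapply(nodes, `[[`, numeric(1), "w")
      pick <- order(ws)[1:2]          # stable: earlier-created node wins ties
      a <- nodes[[pick[1L]]]; b <- nodes[[pick[2L]]]
      leaves <- c(a$leaves, b$leaves)
      depth[leaves] <- depth[leaves] + 1L
      nodes <- c(nodes[-pick], list(list(w = a$w + b$w, leaves = leaves)))
    }
  }
  huffman_canonical(syms, as.integer(depth))
}

#' Derive canonical codes from symbols and code lengths
#'
#' @param symbols character vector.
#' @param lengths positive integer code lengths, one per symbol.
#' @return Code table in canonical order (see [huffman_build()]).
#' @export
huffman_canonical <- function(symbols, lengths) {
  lengths <- as.integer(lengths)
  if (length(symbols) != length(lengths) || any(lengths <= 0))
    stop_corrupt("invalid Huffman length table")
  o <- order(lengths, symbols, method = "radix")
  symbols <- symbols[o]
  lengths <- lengths[o]
  k <- length(symbols)
  codes <- numeric(k)
  if (k >= 1L) codes[1L] <- 0
  if (k >= 2L) {
    for (i in 2:k) codes[i] <- (codes[i - 1L] + 1) * 2^(lengths[i] - lengths[i - 1L])
  }
  if (any(codes >= 2^lengths))
    stop_corrupt("Huffman lengths violate the Kraft inequality")
  bitstr <- vapply(seq_len(k), function(i) {
    bits <- integer(lengths[i])
    v <- codes[i]
    for (j in lengths[i]:1) { bits[j] <- v %% 2; v <- v %/% 2 }
    paste(bits, collapse = "")
  }, character(1))
  list(symbols = symbols, lengths = lengths, codes = bitstr)
}

#' Huffman-encode a token sequence
#'
#' @param tokens character vector; every token must appear in the table.
#' @param table code table from [huffman_build()].
#' @return A bitstream (list with `bytes`, `bit_count`).
#' @export
huffman_encode <- function(tokens, table) {
  if (length(tokens) == 0L) return(list(bytes = raw(0), bit_count = 0L))
  idx <- match(tokens, table$symbols)
  if (anyNA(idx)) stop("token absent from Huffman table")
  s <- paste(table$codes[idx], collapse = "")
  bits_to_raw(as.integer(strsplit(s, "", fixed = TRUE)[[1L]]))
}

#' Decode a Huffman bitstream
#'
#' Canonical decoding: at each length the accumulated code value is compared
#' with the first code of that length.
#'
#' @param bits bitstream (list with `bytes`, `bit_count`) or raw vector.
#' @param table code table from [huffman_build()].
#' @param n number of tokens to decode.
#' @return Character vector of `n` tokens.
#' @export
huffman_decode <- function(bits, table, n) {
  n <- as.integer(n)
  if (n == 0L) return(character(0))
  if (is.raw(bits)) bits <- list(bytes = bits, bit_count = 8L * length(bits))
  bv <- raw_to_bits(bits$bytes, bits$bit_count)
  maxlen <- max(table$lengths)
  first_code <- rep(NA_real_, maxlen)   # first canonical code of each length
  count <- integer(maxlen)
  start <- integer(maxlen)              # canonical index of first symbol
  codes_num <- vapply(seq_along(table$codes), function(i)
    sum(as.integer(strsplit(table$codes[i], "", fixed = TRUE)[[1L]]) *
          2^((table$lengths[i] - 1):0)), numeric(1))
  for (l in seq_len(maxlen)) {
    at <- which(table$lengths == l)
    count[l] <- length(at)
    if (count[l] > 0L) { first_code[l] <- codes_num[at[1L]]; start[l] <- at[1L] }
  }
  out <- character(n)
  p <- 0L
  nb <- length(bv)
  for (i in seq_len(n)) {
    code <- 0
    l <- 0L
    repeat {
      l <- l + 1L
      p <- p + 1L
      if (p > nb) stop_corrupt("Huffman bitstream exhausted")
      code <- code * 2 + bv[p]
      if (l > maxlen) stop_corrupt("invalid Huffman code in stream")
      if (count[l] > 0L && code >= first_code[l] && code < first_code[l] + count[l]) {
        out[i] <- table$symbols[start[l] + (code - first_code[l])]
        break
      }
    }
  }
  out
}

# 2-bit DNA packing ------------------------------------------------------------

TWOBIT_ALPHABET <- c("A", "C", "G", "T")
.twobit_lut <- local({
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt("A") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L
  lut
})

#' Pack an ACGT string into 2 bits per base
#'
#' Fixed mapping A=00, C=01, G=10, T=11, packed MSB-first. Any other
#' character (including N) is an error; callers excise N positions first.
#'
#' @param seq a single character string over {A,C,G,T}.
#' @return A bitstream (list with `bytes`, `bit_count = 2 * nchar(seq)`).
#' @export
pack_2bit <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return(list(bytes = raw(0), bit_count = 0L))
  v <- .twobit_lut[as.integer(charToRaw(seq)) + 1L]
  if (anyNA(v)) stop("pack_2bit: character outside {A,C,G,T}")
  bits <- as.vector(rbind(v %/% 2L, v %% 2L))
  bits_to_raw(bits)
}

#' Unpack a 2-bit stream back into an ACGT string
#'
#' @param bits bitstream or raw vector from [pack_2bit()].
#' @param n number of bases to recover.
#' @return Character string of length `n`.
#' @export
unpack_2bit <- function(bits, n) {
  n <- as.integer(n)
  if (n == 0L) return("")
  bytes <- if (is.raw(bits)) bits else bits$bytes
  bv <- raw_to_bits(bytes, 2L * n)
  m <- matrix(bv, nrow = 2L)
  v <- m[1L, ] * 2L + m[2L, ]
  rawToChar(charToRaw("ACGT")[v + 1L])
}
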