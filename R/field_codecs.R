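# Per-field codecs.
#
# Each mandatory SAM column (and the optional-tag column) is encoded into an
# independent stream by a codec matched to its statistics. Every codec is
# exactly invertible; when a column does not fit a codec's assumptions, or the
# specialized encoding would be larger than the raw text, the stream falls
# back down a ladder (specialized -> token RLE -> raw) so that the worst case
# is the raw column plus a small fixed header. A candidate representation is
# accepted only after a decode round-trip reproduces the column exactly.

# field ids
FIELD_IDS <- c(HEADER = 0L, QNAME = 1L, FLAG = 2L, RNAME = 3L, POS = 4L,
               MAPQ = 5L, CIGAR = 6L, MRNM = 7L, MPOS = 8L, ISIZE = 9L,
               SEQ = 10L, QUAL = 11L, TAGS = 12L)

# codec ids
CODEC <- c(RAW = 0L, RLE_TOKEN = 1L, QNAME_TEMPLATE = 2L, INT_DELTA_RLE = 3L,
           MRNM_BITMAP = 4L, CONST_ZERO = 5L, SEQ_2BIT = 6L,
           SEQ_NSIDECAR = 7L, TAGS_HUFFMAN = 8L, QUAL_RLE = 9L)

new_stream <- function(field_id, codec_id, payload, params = raw(0),
                       fallback = FALSE, n_records = 0L) {
  structure(list(field_id = as.integer(field_id),
                 codec_id = as.integer(codec_id),
                 fallback = isTRUE(fallback),
                 params = params,
                 payload = payload,
                 n_records = as.integer(n_records)),
            class = "encoded_stream")
}

stream_size <- function(s) length(s$params) + length(s$payload)

#' @export
print.encoded_stream <- function(x, ...) {
  cat(sprintf("<encoded_stream field=%s codec=%s%s: %d params + %d payload bytes, n=%d>\n",
              names(FIELD_IDS)[match(x$field_id, FIELD_IDS)],
              names(CODEC)[match(x$codec_id, CODEC)],
              if (x$fallback) " (fallback)" else "",
              length(x$params), length(x$payload), x$n_records))
  invisible(x)
}

# Raw fallback -----------------------------------------------------------------

# Raw payload is the newline-joined original column text (unambiguous because
# field values cannot contain newline bytes).
raw_stream <- function(col, field_id) {
  payload <- if (length(col) == 0L) raw(0) else charToRaw(paste(col, collapse = "\n"))
  new_stream(field_id, CODEC[["RAW"]], payload, fallback = TRUE,
             n_records = length(col))
}

decode_raw_column <- function(payload, n) {
  if (n == 0L) return(character(0))
  parts <- strsplit(rawToChar(payload), "\n", fixed = TRUE, useBytes = TRUE)[[1L]]
  if (length(parts) > n) stop_corrupt("raw column has too many values")
  c(parts, rep("", n - length(parts)))   # strsplit drops trailing empties
}

# Fallback ladder: accept the first candidate (in order) that round-trips and
# is no larger than the raw representation.
choose_stream <- function(col, field_id, candidates) {
  rs <- raw_stream(col, field_id)
  for (cand in candidates) {
    if (is.null(cand)) next
    if (stream_size(cand) > stream_size(rs)) next
    ok <- tryCatch(identical(decode_field(cand), col), error = function(e) FALSE)
    if (ok) return(cand)
  }
  rs
}

# Token RLE (FLAG, RNAME, MAPQ, CIGAR, MPOS) -----------------------------------

rle_token_stream <- function(col, field_id) {
  r <- rle_encode(col)
  vals <- r$values
  payload <- c(varint_encode(length(vals)),
               varint_encode(r$counts),
               varint_encode(nchar(vals, type = "bytes")),
               if (length(vals)) charToRaw(paste(vals, collapse = "")) else raw(0))
  new_stream(field_id, CODEC[["RLE_TOKEN"]], payload, n_records = length(col))
}

decode_rle_token <- function(s) {
  p <- s$payload
  h <- varint_decode(p, 1L)
  nruns <- h$values
  counts <- varint_decode(p, nruns, h$offset)
  lens <- varint_decode(p, nruns, counts$offset)
  total <- sum(lens$values)
  if (lens$offset + total - 1L > length(p)) stop_corrupt("truncated RLE values")
  vals <- split_concat(p, lens$values, lens$offset)
  out <- rle_decode(list(values = vals, counts = counts$values))
  if (length(out) != s$n_records) stop_corrupt("RLE record count mismatch")
  out
}

#' Encode a text column with token run-length encoding
#'
#' Used for FLAG, RNAME, MAPQ, CIGAR and MPOS, whose values repeat in long
#' runs in coordinate-sorted files. Falls back to the raw column when runs
#' are absent and RLE would expand.
#'
#' @param col character vector of field values.
#' @param field_id integer field id (see the `FIELD_IDS` constant).
#' @return An `encoded_stream`.
#' @export
encode_rle_text <- function(col, field_id) {
  choose_stream(col, field_id, list(rle_token_stream(col, field_id)))
}

# QUAL: character-level RLE ----------------------------------------------------

# QUAL runs occur *within* strings, so RLE operates on the concatenated
# character stream; per-record string lengths are stored in the params block.
qual_rle_stream <- function(col) {
  lens <- nchar(col, type = "bytes")
  s <- paste(col, collapse = "")
  ch <- charToRaw(s)
  r <- rle(as.integer(ch))
  payload <- c(varint_encode(length(r$values)),
               varint_encode(r$lengths),
               as.raw(r$values))
  new_stream(FIELD_IDS[["QUAL"]], CODEC[["QUAL_RLE"]], payload,
             params = varint_encode(lens), n_records = length(col))
}

decode_qual_rle <- function(s) {
  n <- s$n_records
  lens <- varint_decode(s$params, n)$values
  p <- s$payload
  h <- varint_decode(p, 1L)
  nruns <- h$values
  counts <- varint_decode(p, nruns, h$offset)
  vals_at <- counts$offset
  if (vals_at + nruns - 1L > length(p)) stop_corrupt("truncated QUAL runs")
  chars <- p[seq.int(vals_at, length.out = nruns)]
  if (any(counts$values <= 0)) stop_corrupt("non-positive run count")
  stream <- rep(chars, counts$values)
  if (length(stream) != sum(lens)) stop_corrupt("QUAL length mismatch")
  split_concat(stream, lens, 1L)
}

#' Encode the QUAL column with character-stream run-length encoding
#'
#' @inheritParams encode_rle_text
#' @return An `encoded_stream`.
#' @export
encode_qual <- function(col) {
  choose_stream(col, FIELD_IDS[["QUAL"]],
                list(qual_rle_stream(col),
                     rle_token_stream(col, FIELD_IDS[["QUAL"]])))
}

# POS / ISIZE: delta + RLE integer coding --------------------------------------

# canonical decimal spellings: what sprintf("%.0f", as.numeric(x)) reproduces
canonical_uint <- function(col) grepl("^(0|[1-9][0-9]{0,14})$", col)
canonical_int <- function(col) grepl("^(0|-?[1-9][0-9]{0,14})$", col)

int_delta_rle_stream <- function(col, field_id) {
  n <- length(col)
  if (n == 0L)
    return(new_stream(field_id, CODEC[["INT_DELTA_RLE"]], raw(0), n_records = 0L))
  v <- as.double(col)
  d <- delta_encode(v)
  r <- rle(d$diffs)
  payload <- c(varint_encode(zigzag(d$first)),
               varint_encode(length(r$values)),
               varint_encode(r$lengths),
               varint_encode(zigzag(r$values)))
  new_stream(field_id, CODEC[["INT_DELTA_RLE"]], payload, n_records = n)
}

decode_int_delta_rle <- function(s) {
  n <- s$n_records
  if (n == 0L) return(character(0))
  p <- s$payload
  f <- varint_decode(p, 1L)
  h <- varint_decode(p, 1L, f$offset)
  nruns <- h$values
  counts <- varint_decode(p, nruns, h$offset)
  dvals <- varint_decode(p, nruns, counts$offset)
  diffs <- rep(unzigzag(dvals$values), counts$values)
  vals <- delta_decode(unzigzag(f$values), diffs)
  if (length(vals) != n) stop_corrupt("integer stream record count mismatch")
  sprintf("%.0f", vals)
}

#' Encode the POS column with delta plus run-length coding
#'
#' Coordinate-sorted positions have small, often-repeated successive
#' differences; these are zigzag-folded and stored as run-length-compressed
#' varints. Values that would not re-render canonically (leading zeros,
#' more than 15 digits) force raw fallback, preserving losslessness.
#'
#' @inheritParams encode_rle_text
#' @return An `encoded_stream`.
#' @export
encode_pos <- function(col) {
  cand <- if (all(canonical_uint(col)))
    int_delta_rle_stream(col, FIELD_IDS[["POS"]]) else NULL
  choose_stream(col, FIELD_IDS[["POS"]],
                list(cand, rle_token_stream(col, FIELD_IDS[["POS"]])))
}

#' Encode the ISIZE column
#'
#' Most coordinate-sorted single-end files carry a constant ISIZE of zero,
#' which is recorded as a zero-byte constant stream. Otherwise the column
#' takes the signed-integer delta path, then token RLE, then raw -- the first
#' representation that round-trips without expansion wins.
#'
#' @inheritParams encode_rle_text
#' @return An `encoded_stream`.
#' @export
encode_isize <- function(col) {
  if (all(col == "0"))
    return(new_stream(FIELD_IDS[["ISIZE"]], CODEC[["CONST_ZERO"]], raw(0),
                      n_records = length(col)))
  cand <- if (all(canonical_int(col)))
    int_delta_rle_stream(col, FIELD_IDS[["ISIZE"]]) else NULL
  choose_stream(col, FIELD_IDS[["ISIZE"]],
                list(cand, rle_token_stream(col, FIELD_IDS[["ISIZE"]])))
}

# MRNM: 1-bit dictionary -------------------------------------------------------

#' Encode the mate reference name column
#'
#' When every value is `=` or `*` (the dominant case in sorted paired files)
#' the column is stored as a 1-bit-per-record bitmap (`=` is 0); otherwise it
#' falls back to token RLE, then raw.
#'
#' @inheritParams encode_rle_text
#' @return An `encoded_stream`.
#' @export
encode_mrnm <- function(col) {
  if (all(col %in% c("=", "*"))) {
    bs <- bits_to_raw(as.integer(col == "*"))
    return(new_stream(FIELD_IDS[["MRNM"]], CODEC[["MRNM_BITMAP"]], bs$bytes,
                      n_records = length(col)))
  }
  choose_stream(col, FIELD_IDS[["MRNM"]],
                list(rle_token_stream(col, FIELD_IDS[["MRNM"]])))
}

decode_mrnm_bitmap <- function(s) {
  bits <- raw_to_bits(s$payload, s$n_records)
  c("=", "*")[bits + 1L]
}

# QNAME: template + integer slots ----------------------------------------------

# Read names are tokenized into alternating non-digit/digit runs. If all
# records agree on the token structure and on every non-digit token, the
# shared tokens become a template and each digit run becomes a slot encoded
# column-wise (delta + zigzag + varint). Slots whose digit strings do not
# re-render canonically are kept as text; structural disagreement falls back
# to the raw column.

SLOT_NUMERIC <- 0L; SLOT_FIXED_WIDTH <- 1L; SLOT_TEXT <- 2L

qname_template_stream <- function(col) {
  n <- length(col)
  fid <- FIELD_IDS[["QNAME"]]
  if (n == 0L)
    return(new_stream(fid, CODEC[["QNAME_TEMPLATE"]],
                      raw(0), params = varint_encode(0), n_records = 0L))
  toks <- regmatches(col, gregexpr("[0-9]+|[^0-9]+", col))
  tc <- lengths(toks)
  if (any(tc != tc[1L]) || tc[1L] == 0L) return(NULL)
  mat <- matrix(unlist(toks, use.names = FALSE), nrow = tc[1L])
  isdig <- grepl("^[0-9]", mat[, 1L])
  for (r in seq_len(nrow(mat))) {
    row_dig <- startsWith(mat[r, ], "0") | grepl("^[1-9]", mat[r, ])
    if (any(row_dig != isdig[r])) return(NULL)
    if (!isdig[r] && any(mat[r, ] != mat[r, 1L])) return(NULL)
  }
  # params: template structure
  params <- varint_encode(nrow(mat))
  for (r in seq_len(nrow(mat))) {
    if (isdig[r]) {
      params <- c(params, as.raw(1L))
    } else {
      lit <- charToRaw(mat[r, 1L])
      params <- c(params, as.raw(0L), varint_encode(length(lit)), lit)
    }
  }
  # payload: one block per slot row
  payload <- raw(0)
  for (r in which(isdig)) {
    vals <- mat[r, ]
    w <- nchar(vals)
    lead0 <- w > 1L & startsWith(vals, "0")
    if (!any(lead0) && max(w) <= 15L) {
      v <- as.double(vals)
      payload <- c(payload, as.raw(SLOT_NUMERIC),
                   varint_encode(zigzag(c(v[1L], diff(v)))))
    } else if (all(w == w[1L]) && w[1L] <= 15L) {
      v <- as.double(vals)
      payload <- c(payload, as.raw(SLOT_FIXED_WIDTH), varint_encode(w[1L]),
                   varint_encode(zigzag(c(v[1L], diff(v)))))
    } else {
      txt <- charToRaw(paste(vals, collapse = "\n"))
      payload <- c(payload, as.raw(SLOT_TEXT), varint_encode(length(txt)), txt)
    }
  }
  new_stream(fid, CODEC[["QNAME_TEMPLATE"]], payload, params = params,
             n_records = n)
}

decode_qname_template <- function(s) {
  n <- s$n_records
  pr <- s$params
  h <- varint_decode(pr, 1L)
  nrows <- h$values
  if (n == 0L) return(character(0))
  off <- h$offset
  rows <- vector("list", nrows)
  isdig <- logical(nrows)
  for (r in seq_len(nrows)) {
    type <- as.integer(pr[off]); off <- off + 1L
    if (type == 1L) {
      isdig[r] <- TRUE
    } else {
      ln <- varint_decode(pr, 1L, off)
      off <- ln$offset
      lit <- rawToChar(pr[seq.int(off, length.out = ln$values)])
      off <- off + ln$values
      rows[[r]] <- lit
    }
  }
  p <- s$payload
  off <- 1L
  for (r in which(isdig)) {
    mode <- as.integer(p[off]); off <- off + 1L
    if (mode == SLOT_NUMERIC || mode == SLOT_FIXED_WIDTH) {
      w <- NULL
      if (mode == SLOT_FIXED_WIDTH) {
        wd <- varint_decode(p, 1L, off); w <- wd$values; off <- wd$offset
      }
      zz <- varint_decode(p, n, off); off <- zz$offset
      d <- unzigzag(zz$values)
      vals <- cumsum(d)
      rows[[r]] <- if (is.null(w)) sprintf("%.0f", vals)
                   else sprintf(paste0("%0", w, ".0f"), vals)
    } else if (mode == SLOT_TEXT) {
      ln <- varint_decode(p, 1L, off); off <- ln$offset
      txt <- rawToChar(p[seq.int(off, length.out = ln$values)])
      off <- off + ln$values
      vals <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
      rows[[r]] <- c(vals, rep("", n - length(vals)))
    } else stop_corrupt("unknown QNAME slot mode")
  }
  out <- do.call(paste0, rows)
  if (length(out) == 1L && n > 1L) out <- rep(out, n)   # all-literal template
  if (length(out) != n) stop_corrupt("QNAME record count mismatch")
  out
}

#' Encode the QNAME column as a shared template plus integer slots
#'
#' @inheritParams encode_rle_text
#' @return An `encoded_stream`.
#' @export
encode_qname <- function(col) {
  choose_stream(col, FIELD_IDS[["QNAME"]], list(qname_template_stream(col)))
}

# SEQ: 2-bit packing + N sidecar -----------------------------------------------

#' Encode the SEQ column as 2-bit packed bases with an N-position sidecar
#'
#' Per-record lengths go in the params block; the payload is exactly
#' `ceiling(base_count / 4)` bytes of packed ACGT. N positions are excised
#' and stored in a separate sidecar stream as (record-index delta,
#' within-record position delta) varint pairs. Any record containing a
#' character outside ACGTN (including the `*` placeholder) forces raw
#' fallback for the whole column.
#'
#' @inheritParams encode_rle_text
#' @return List of two `encoded_stream`s: `base` and `sidecar`.
#' @export
encode_seq <- function(col) {
  n <- length(col)
  fid <- FIELD_IDS[["SEQ"]]
  empty_sidecar <- new_stream(fid, CODEC[["SEQ_NSIDECAR"]],
                              varint_encode(0), n_records = n)
  if (n > 0L && !all(grepl("^[ACGTN]+$", col)))
    return(list(base = raw_stream(col, fid), sidecar = empty_sidecar))
  lens <- nchar(col, type = "bytes")
  s <- paste(col, collapse = "")
  npos <- as.integer(gregexpr("N", s, fixed = TRUE)[[1L]])
  if (n == 0L || npos[1L] == -1L) npos <- integer(0)
  # recover (record, within-record) coordinates, 0-based
  ends <- cumsum(lens)
  p0 <- npos - 1L
  rec0 <- findInterval(p0, ends - 0.5)
  within0 <- p0 - c(0L, ends)[rec0 + 1L]
  prev_rec <- c(-1L, rec0[-length(rec0)])
  same <- rec0 == prev_rec
  pos_delta <- ifelse(same, within0 - c(0L, within0[-length(within0)]), within0)
  rec_delta <- c(rec0[1L], diff(rec0))
  if (length(npos) == 0L) { rec_delta <- numeric(0); pos_delta <- numeric(0) }
  sidecar_payload <- c(varint_encode(length(npos)),
                       varint_encode(rec_delta), varint_encode(pos_delta))
  bases <- gsub("N", "", s, fixed = TRUE)
  packed <- pack_2bit(bases)
  base <- new_stream(fid, CODEC[["SEQ_2BIT"]], packed$bytes,
                     params = varint_encode(lens), n_records = n)
  sidecar <- new_stream(fid, CODEC[["SEQ_NSIDECAR"]], sidecar_payload,
                        n_records = n)
  # expansion guard (pack_2bit quarters the text; guard is for form's sake)
  rs <- raw_stream(col, fid)
  if (stream_size(base) + stream_size(sidecar) > stream_size(rs))
    return(list(base = rs, sidecar = empty_sidecar))
  list(base = base, sidecar = sidecar)
}

decode_seq <- function(base, sidecar) {
  if (base$codec_id == CODEC[["RAW"]])
    return(decode_raw_column(base$payload, base$n_records))
  n <- base$n_records
  if (n == 0L) return(character(0))
  lens <- varint_decode(base$params, n)$values
  sp <- sidecar$payload
  h <- varint_decode(sp, 1L)
  nN <- h$values
  rd <- varint_decode(sp, nN, h$offset)
  pd <- varint_decode(sp, nN, rd$offset)
  total <- sum(lens)
  nbases <- total - nN
  bases <- unpack_2bit(base$payload, nbases)
  if (nN > 0) {
    rec0 <- cumsum(rd$values)
    same <- c(FALSE, diff(rec0) == 0)
    within0 <- numeric(nN)
    for (i in seq_len(nN))   # prefix-sum within records
      within0[i] <- if (same[i]) within0[i - 1L] + pd$values[i] else pd$values[i]
    starts0 <- c(0, cumsum(lens))
    gpos <- starts0[rec0 + 1L] + within0   # 0-based global positions
    if (any(gpos >= total)) stop_corrupt("N position out of range")
    isN <- logical(total)
    isN[gpos + 1] <- TRUE
    res <- raw(total)
    res[isN] <- charToRaw("N")
    res[!isN] <- charToRaw(bases)
    full <- rawToChar(res)
  } else {
    full <- bases
  }
  split_concat(charToRaw(full), lens, 1L)
}

# TAGS: Huffman-coded TAG/VTYPE + verbatim values ------------------------------

serialize_huffman_table <- function(tab) {
  out <- varint_encode(length(tab$symbols))
  for (i in seq_along(tab$symbols)) {
    b <- charToRaw(tab$symbols[i])
    out <- c(out, varint_encode(length(b)), b, varint_encode(tab$lengths[i]))
  }
  out
}

deserialize_huffman_table <- function(bytes, offset) {
  h <- varint_decode(bytes, 1L, offset)
  k <- h$values
  off <- h$offset
  syms <- character(k); lens <- integer(k)
  for (i in seq_len(k)) {
    ln <- varint_decode(bytes, 1L, off); off <- ln$offset
    syms[i] <- rawToChar(bytes[seq.int(off, length.out = ln$values)])
    off <- off + ln$values
    cl <- varint_decode(bytes, 1L, off); off <- cl$offset
    lens[i] <- cl$values
  }
  list(table = huffman_canonical(syms, lens), offset = off)
}

tags_huffman_stream <- function(opt) {
  n <- length(opt)
  fid <- FIELD_IDS[["TAGS"]]
  counts <- lengths(opt)
  all_tok <- unlist(opt, use.names = FALSE)
  if (length(all_tok) > 0L) {
    ok <- all(nchar(all_tok) >= 5L & substr(all_tok, 3L, 3L) == ":" &
                substr(all_tok, 5L, 5L) == ":")
    if (!ok) return(NULL)
  }
  payload <- varint_encode(counts)
  if (length(all_tok) == 0L) {
    params <- as.raw(0L)   # no code tables
    return(new_stream(fid, CODEC[["TAGS_HUFFMAN"]], payload, params = params,
                      n_records = n))
  }
  tag <- substr(all_tok, 1L, 2L)
  vt <- substr(all_tok, 4L, 4L)
  val <- substr(all_tok, 6L, nchar(all_tok))
  ttab <- huffman_build(table(tag))
  vtab <- huffman_build(table(vt))
  params <- c(as.raw(1L), serialize_huffman_table(ttab),
              serialize_huffman_table(vtab))
  tbits <- huffman_encode(tag, ttab)
  vbits <- huffman_encode(vt, vtab)
  vraw <- if (any(nchar(val) > 0)) charToRaw(paste(val, collapse = "")) else raw(0)
  payload <- c(payload,
               varint_encode(length(tbits$bytes)), tbits$bytes,
               varint_encode(length(vbits$bytes)), vbits$bytes,
               varint_encode(nchar(val, type = "bytes")), vraw)
  new_stream(fid, CODEC[["TAGS_HUFFMAN"]], payload, params = params,
             n_records = n)
}

decode_tags_huffman <- function(s) {
  n <- s$n_records
  cnt <- varint_decode(s$payload, n)
  counts <- cnt$values
  m <- sum(counts)
  if (m == 0) return(split_groups(character(0), counts))
  has_tables <- as.integer(s$params[1L])
  if (has_tables != 1L) stop_corrupt("tag stream missing code tables")
  tt <- deserialize_huffman_table(s$params, 2L)
  vt <- deserialize_huffman_table(s$params, tt$offset)
  p <- s$payload
  off <- cnt$offset
  tl <- varint_decode(p, 1L, off); off <- tl$offset
  tbytes <- p[seq.int(off, length.out = tl$values)]; off <- off + tl$values
  vl <- varint_decode(p, 1L, off); off <- vl$offset
  vbytes <- p[seq.int(off, length.out = vl$values)]; off <- off + vl$values
  vlens <- varint_decode(p, m, off)
  vals <- split_concat(p, vlens$values, vlens$offset)
  tags <- huffman_decode(tbytes, tt$table, m)
  vts <- huffman_decode(vbytes, vt$table, m)
  toks <- paste0(tags, ":", vts, ":", vals)
  split_groups(toks, counts)
}

# raw fallback for the optional column: records joined by newline, tokens by TAB
raw_tags_stream <- function(opt) {
  n <- length(opt)
  payload <- if (n == 0L) raw(0) else
    charToRaw(paste(vapply(opt, paste, character(1), collapse = "\t"),
                    collapse = "\n"))
  new_stream(FIELD_IDS[["TAGS"]], CODEC[["RAW"]], payload, fallback = TRUE,
             n_records = n)
}

decode_raw_tags <- function(s) {
  n <- s$n_records
  if (n == 0L) return(list())
  lines <- decode_raw_column(s$payload, n)
  lapply(strsplit(lines, "\t", fixed = TRUE),
         function(x) if (length(x) == 1L && x == "") character(0) else x)
}

#' Encode the optional-field column
#'
#' TAG codes and VTYPE characters come from small alphabets and are Huffman
#' coded with per-file canonical tables; VALUE text is kept verbatim with
#' length prefixes. Tag order within each record is preserved exactly.
#'
#' @param opt list of character vectors, one per record, each element a
#'   `TAG:VTYPE:VALUE` token.
#' @return An `encoded_stream`.
#' @export
encode_tags <- function(opt) {
  cand <- tags_huffman_stream(opt)
  rs <- raw_tags_stream(opt)
  if (!is.null(cand) && stream_size(cand) <= stream_size(rs)) {
    ok <- tryCatch(identical(decode_field(cand), opt), error = function(e) FALSE)
    if (ok) return(cand)
  }
  rs
}

# Dispatch ---------------------------------------------------------------------

#' Decode one encoded field stream back into its column
#'
#' Exact inverse of the field encoders. SEQ streams need their N-position
#' sidecar, passed as `sidecar`.
#'
#' @param stream an `encoded_stream`.
#' @param sidecar the SEQ N-sidecar stream, when decoding a 2-bit SEQ stream.
#' @return A character vector (or, for the tag column, a list of character
#'   vectors) of length `n_records`.
#' @export
decode_field <- function(stream, sidecar = NULL) {
  cid <- stream$codec_id
  if (cid == CODEC[["RAW"]]) {
    if (stream$field_id == FIELD_IDS[["TAGS"]]) return(decode_raw_tags(stream))
    return(decode_raw_column(stream$payload, stream$n_records))
  }
  if (cid == CODEC[["RLE_TOKEN"]]) return(decode_rle_token(stream))
  if (cid == CODEC[["QUAL_RLE"]]) return(decode_qual_rle(stream))
  if (cid == CODEC[["INT_DELTA_RLE"]]) return(decode_int_delta_rle(stream))
  if (cid == CODEC[["CONST_ZERO"]]) return(rep("0", stream$n_records))
  if (cid == CODEC[["MRNM_BITMAP"]]) return(decode_mrnm_bitmap(stream))
  if (cid == CODEC[["QNAME_TEMPLATE"]]) return(decode_qname_template(stream))
  if (cid == CODEC[["SEQ_2BIT"]]) {
    if (is.null(sidecar)) stop_corrupt("SEQ stream requires its N sidecar")
    return(decode_seq(stream, sidecar))
  }
  if (cid == CODEC[["TAGS_HUFFMAN"]]) return(decode_tags_huffman(stream))
  stop_corrupt(sprintf("unknown codec id %d", cid))
}

#' Encode all columns of a document
#'
#' Applies the per-field strategy to each of the 12 columns; each encoder
#' sees only its own column.
#'
#' @param doc a `sam_document`.
#' @return Ordered list of `encoded_stream`s (SEQ contributes a base stream
#'   and an N sidecar).
#' @export
encode_document <- function(doc) {
  cols <- sam_transpose(doc)
  seqs <- encode_seq(cols$SEQ)
  list(qname = encode_qname(cols$QNAME),
       flag = encode_rle_text(cols$FLAG, FIELD_IDS[["FLAG"]]),
       rname = encode_rle_text(cols$RNAME, FIELD_IDS[["RNAME"]]),
       pos = encode_pos(cols$POS),
       mapq = encode_rle_text(cols$MAPQ, FIELD_IDS[["MAPQ"]]),
       cigar = encode_rle_text(cols$CIGAR, FIELD_IDS[["CIGAR"]]),
       mrnm = encode_mrnm(cols$MRNM),
       mpos = encode_rle_text(cols$MPOS, FIELD_IDS[["MPOS"]]),
       isize = encode_isize(cols$ISIZE),
       seq = seqs$base,
       seqn = seqs$sidecar,
       qual = encode_qual(cols$QUAL),
       tags = encode_tags(cols$OPT))
}

#' Decode a full stream set back into columns
#'
#' @param streams named list as produced by [encode_document()].
#' @param n_records expected record count; all streams must agree.
#' @return List with `columns` (11 mandatory) and `opt`.
#' @export
decode_document_streams <- function(streams, n_records) {
  ns <- vapply(streams, `[[`, integer(1), "n_records")
  if (any(ns != n_records))
    stop_corrupt("streams disagree on record count")
  columns <- stats::setNames(vector("list", 11L), SAM_FIELDS)
  columns$QNAME <- decode_field(streams$qname)
  columns$FLAG <- decode_field(streams$flag)
  columns$RNAME <- decode_field(streams$rname)
  columns$POS <- decode_field(streams$pos)
  columns$MAPQ <- decode_field(streams$mapq)
  columns$CIGAR <- decode_field(streams$cigar)
  columns$MRNM <- decode_field(streams$mrnm)
  columns$MPOS <- decode_field(streams$mpos)
  columns$ISIZE <- decode_field(streams$isize)
  columns$SEQ <- decode_field(streams$seq, sidecar = streams$seqn)
  columns$QUAL <- decode_field(streams$qual)
  list(columns = columns, opt = decode_field(streams$tags))
}

# Helpers ----------------------------------------------------------------------

# split a concatenated byte payload into strings of the given byte lengths
split_concat <- function(bytes, lens, offset) {
  k <- length(lens)
  if (k == 0L) return(character(0))
  total <- sum(lens)
  if (total == 0) return(rep("", k))
  if (offset + total - 1 > length(bytes)) stop_corrupt("truncated value block")
  s <- rawToChar(bytes[seq.int(offset, length.out = total)])
  ends <- cumsum(lens)
  starts <- c(1, ends[-k] + 1)
  substring(s, starts, ends)
}

# split a flat token vector into per-record groups of the given sizes
split_groups <- function(tokens, counts) {
  n <- length(counts)
  if (n == 0L) return(list())
  idx <- rep(seq_len(n), counts)
  out <- rep(list(character(0)), n)
  if (length(tokens) > 0L) {
    grouped <- split(tokens, factor(idx, levels = seq_len(n)))
    out <- unname(grouped)
  }
  out
}
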