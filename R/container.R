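# Container format.
#
# Single-file layout (.smz):
#   magic "SMZ1" | version byte | mode byte (0 = fielded, 1 = raw document)
#   | backend byte (0 none, 1 deflate, 2 bzip2, 3 lzma)
#   | body (post-compressed unless backend 0) | CRC32 of the uncompressed body
#
# Fielded body:
#   n_records varint | newline byte (0 LF, 1 CRLF) | trailing-newline byte
#   | header blob (varint length + bytes) | n_streams varint | framed streams
#
# Stream frame: field_id byte | codec_id byte | fallback byte
#   | params length varint | params | payload length varint | payload
#   | CRC32 of payload
#
# Directory mode mirrors the one-file-per-field workflow: "header.smzf"
# carries the metadata and header blob, and each field stream goes to its own
# "<field>.smzf", so an external compressor can be pointed at the files.

CONTAINER_MAGIC <- charToRaw("SMZ1")
FIELDFILE_MAGIC <- charToRaw("SMZF")
HEADERFILE_MAGIC <- charToRaw("SMZH")
CONTAINER_VERSION <- 1L
MODE_FIELDED <- 0L
MODE_RAWDOC <- 1L

BACKENDS <- c(none = 0L, deflate = 1L, bzip2 = 2L, lzma = 3L)
.backend_type <- c("none", "gzip", "bzip2", "xz")

STREAM_ORDER <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm",
                  "mpos", "isize", "seq", "seqn", "qual", "tags")

backend_compress <- function(bytes, backend_id) {
  if (backend_id == 0L) return(bytes)
  memCompress(bytes, type = .backend_type[backend_id + 1L])
}

backend_decompress <- function(bytes, backend_id) {
  if (backend_id == 0L) return(bytes)
  tryCatch(memDecompress(bytes, type = .backend_type[backend_id + 1L],
                         asChar = FALSE),
           error = function(e) stop_corrupt(
             paste0("post-compression payload corrupt: ", conditionMessage(e)),
             class = "samzip_truncated"))
}

frame_stream <- function(s) {
  c(as.raw(s$field_id), as.raw(s$codec_id), as.raw(as.integer(s$fallback)),
    varint_encode(length(s$params)), s$params,
    varint_encode(length(s$payload)), s$payload,
    crc32(s$payload))
}

unframe_stream <- function(bytes, offset, n_records) {
  need <- function(k) if (offset + k - 1L > length(bytes))
    stop_corrupt("truncated stream frame", class = "samzip_truncated")
  need(3L)
  field_id <- as.integer(bytes[offset])
  codec_id <- as.integer(bytes[offset + 1L])
  fallback <- as.integer(bytes[offset + 2L]) == 1L
  offset <- offset + 3L
  pl <- varint_decode(bytes, 1L, offset); offset <- pl$offset
  need(pl$values)
  params <- bytes[seq.int(offset, length.out = pl$values)]
  offset <- offset + pl$values
  yl <- varint_decode(bytes, 1L, offset); offset <- yl$offset
  need(yl$values + 4)
  payload <- bytes[seq.int(offset, length.out = yl$values)]
  offset <- offset + yl$values
  stored_crc <- bytes[seq.int(offset, length.out = 4L)]
  offset <- offset + 4L
  if (!identical(crc32(payload), stored_crc))
    stop_corrupt("stream payload CRC mismatch", class = "samzip_crc")
  list(stream = new_stream(field_id, codec_id, payload, params = params,
                           fallback = fallback, n_records = n_records),
       offset = offset)
}

#' Serialize encoded streams into a container
#'
#' @param streams named list of `encoded_stream`s from [encode_document()].
#' @param header_lines character vector of verbatim header lines.
#' @param n_records record count shared by all streams.
#' @param newline `"LF"` or `"CRLF"`.
#' @param trailing_newline whether the last line is terminated.
#' @param post post-compression backend: `"none"`, `"deflate"`, `"bzip2"` or
#'   `"lzma"`. Applied to the whole body in single-file mode.
#' @param dir if non-NULL, write one file per field into this directory
#'   (created if needed) instead of returning a single byte sequence.
#' @return Raw vector (single-file mode) or, invisibly, the directory path.
#' @export
write_container <- function(streams, header_lines, n_records,
                            newline = "LF", trailing_newline = TRUE,
                            post = "none", dir = NULL) {
  backend_id <- BACKENDS[[match.arg(post, names(BACKENDS))]]
  header_blob <- if (length(header_lines)) charToRaw(paste(header_lines, collapse = "\n")) else raw(0)
  meta <- c(varint_encode(n_records),
            as.raw(as.integer(newline == "CRLF")),
            as.raw(as.integer(trailing_newline)),
            varint_encode(length(header_blob)), header_blob)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    hbody <- backend_compress(meta, backend_id)
    writeBin(c(HEADERFILE_MAGIC, as.raw(CONTAINER_VERSION), as.raw(backend_id),
               hbody, crc32(meta)),
             file.path(dir, "header.smzf"))
    for (nm in STREAM_ORDER) {
      fr <- frame_stream(streams[[nm]])
      body <- backend_compress(fr, backend_id)
      writeBin(c(FIELDFILE_MAGIC, as.raw(CONTAINER_VERSION), as.raw(backend_id),
                 body, crc32(fr)),
               file.path(dir, paste0(nm, ".smzf")))
    }
    return(invisible(dir))
  }
  frames <- do.call(c, unname(lapply(streams[STREAM_ORDER], frame_stream)))
  body <- c(meta, varint_encode(length(STREAM_ORDER)), frames)
  unname(c(CONTAINER_MAGIC, as.raw(CONTAINER_VERSION), as.raw(MODE_FIELDED),
           as.raw(backend_id), backend_compress(body, backend_id), crc32(body)))
}

write_rawdoc_container <- function(doc_bytes, post = "none") {
  backend_id <- BACKENDS[[match.arg(post, names(BACKENDS))]]
  body <- c(varint_encode(length(doc_bytes)), doc_bytes)
  c(CONTAINER_MAGIC, as.raw(CONTAINER_VERSION), as.raw(MODE_RAWDOC),
    as.raw(backend_id), backend_compress(body, backend_id), crc32(body))
}

#' Read a container back into its stream set and metadata
#'
#' Accepts single-file container bytes (or a path to one), or a directory
#' written in per-field-file mode. Verifies magic, version and all checksums.
#'
#' @param x raw vector, path to a `.smz` file, or directory path.
#' @return List with `mode`, and for fielded containers `streams`,
#'   `header_lines`, `n_records`, `newline`, `trailing_newline`; for
#'   raw-document containers `doc_bytes`.
#' @export
read_container <- function(x) {
  if (is.character(x) && length(x) == 1L && dir.exists(x))
    return(read_container_dir(x))
  bytes <- if (is.raw(x)) x else readBin(x, "raw", file.size(x))
  if (length(bytes) < 12L)
    stop_corrupt("container truncated", class = "samzip_truncated")
  if (!identical(bytes[1:4], CONTAINER_MAGIC))
    stop_corrupt("bad container magic", class = "samzip_bad_magic")
  version <- as.integer(bytes[5L])
  if (version != CONTAINER_VERSION)
    stop_corrupt(sprintf("unsupported container version %d", version),
                 class = "samzip_bad_version")
  mode <- as.integer(bytes[6L])
  backend_id <- as.integer(bytes[7L])
  if (!backend_id %in% BACKENDS) stop_corrupt("unknown post-compression backend")
  comp <- bytes[seq.int(8L, length(bytes) - 4L)]
  stored_crc <- bytes[seq.int(length(bytes) - 3L, length(bytes))]
  body <- backend_decompress(comp, backend_id)
  if (!identical(crc32(body), stored_crc))
    stop_corrupt("container body CRC mismatch", class = "samzip_crc")
  if (mode == MODE_RAWDOC) {
    ln <- varint_decode(body, 1L)
    if (ln$offset + ln$values - 1L > length(body))
      stop_corrupt("container truncated", class = "samzip_truncated")
    return(list(mode = "rawdoc", backend = names(BACKENDS)[backend_id + 1L],
                doc_bytes = body[seq.int(ln$offset, length.out = ln$values)]))
  }
  if (mode != MODE_FIELDED) stop_corrupt("unknown container mode")
  parsed <- parse_container_meta(body)
  off <- parsed$offset
  ns <- varint_decode(body, 1L, off)
  off <- ns$offset
  streams <- vector("list", ns$values)
  for (i in seq_len(ns$values)) {
    u <- unframe_stream(body, off, parsed$n_records)
    streams[[i]] <- u$stream
    off <- u$offset
  }
  if (ns$values != length(STREAM_ORDER))
    stop_corrupt("unexpected stream count")
  names(streams) <- STREAM_ORDER
  c(list(mode = "fielded", backend = names(BACKENDS)[backend_id + 1L],
         streams = streams), parsed[c("header_lines", "n_records",
                                      "newline", "trailing_newline")])
}

parse_container_meta <- function(body, offset = 1L) {
  nr <- varint_decode(body, 1L, offset)
  offset <- nr$offset
  if (offset + 1L > length(body))
    stop_corrupt("container truncated", class = "samzip_truncated")
  newline <- if (as.integer(body[offset]) == 1L) "CRLF" else "LF"
  trailing <- as.integer(body[offset + 1L]) == 1L
  offset <- offset + 2L
  hl <- varint_decode(body, 1L, offset)
  offset <- hl$offset
  if (offset + hl$values - 1L > length(body))
    stop_corrupt("container truncated", class = "samzip_truncated")
  header_lines <- if (hl$values == 0) character(0) else
    strsplit(rawToChar(body[seq.int(offset, length.out = hl$values)]),
             "\n", fixed = TRUE)[[1L]]
  list(n_records = as.integer(nr$values), newline = newline,
       trailing_newline = trailing, header_lines = header_lines,
       offset = offset + hl$values)
}

read_container_dir <- function(dir) {
  hpath <- file.path(dir, "header.smzf")
  if (!file.exists(hpath)) stop_corrupt("header.smzf missing from directory")
  read_field_file <- function(path, magic) {
    bytes <- readBin(path, "raw", file.size(path))
    if (length(bytes) < 10L)
      stop_corrupt("field file truncated", class = "samzip_truncated")
    if (!identical(bytes[1:4], magic))
      stop_corrupt("bad field-file magic", class = "samzip_bad_magic")
    if (as.integer(bytes[5L]) != CONTAINER_VERSION)
      stop_corrupt("unsupported field-file version", class = "samzip_bad_version")
    backend_id <- as.integer(bytes[6L])
    body <- backend_decompress(bytes[seq.int(7L, length(bytes) - 4L)], backend_id)
    if (!identical(crc32(body), bytes[seq.int(length(bytes) - 3L, length(bytes))]))
      stop_corrupt("field-file CRC mismatch", class = "samzip_crc")
    body
  }
  meta <- parse_container_meta(read_field_file(hpath, HEADERFILE_MAGIC))
  streams <- stats::setNames(vector("list", length(STREAM_ORDER)), STREAM_ORDER)
  for (nm in STREAM_ORDER) {
    path <- file.path(dir, paste0(nm, ".smzf"))
    if (!file.exists(path)) stop_corrupt(sprintf("%s.smzf missing", nm))
    body <- read_field_file(path, FIELDFILE_MAGIC)
    streams[[nm]] <- unframe_stream(body, 1L, meta$n_records)$stream
  }
  c(list(mode = "fielded", backend = "none", streams = streams),
    meta[c("header_lines", "n_records", "newline", "trailing_newline")])
}

# High-level API ---------------------------------------------------------------

#' Compress a SAM file
#'
#' Parses the input, encodes each field column with its specialized codec,
#' frames the streams into a checksummed container and optionally applies a
#' general-purpose post-compression backend. Input that cannot be parsed
#' loss-free (mixed line terminators) is stored verbatim in a raw-document
#' container so the lossless guarantee always holds.
#'
#' @param input raw vector, SAM file path, or single character string.
#' @param output optional path to write the container to.
#' @param post post-compression backend: `"none"`, `"deflate"`, `"bzip2"`,
#'   `"lzma"`.
#' @param dir optional directory for one-file-per-field output.
#' @return The container bytes (invisibly when `output` or `dir` is given),
#'   with a `report` attribute carrying a [compression_report()].
#' @export
sam_compress <- function(input, output = NULL, post = "none", dir = NULL) {
  raw_in <- as_sam_bytes(input)
  t0 <- proc.time()[["elapsed"]]
  doc <- tryCatch(parse_sam(raw_in), samzip_mixed_newlines = function(e) NULL)
  if (is.null(doc)) {
    out <- write_rawdoc_container(raw_in, post = post)
    t1 <- proc.time()[["elapsed"]]
    attr(out, "report") <- compression_report(
      original_bytes = length(raw_in),
      encoded_bytes = length(raw_in),
      final_bytes = length(out),
      per_field = c(rawdoc = length(raw_in)),
      encode_seconds = t1 - t0, decode_seconds = NA_real_)
    if (!is.null(output)) { writeBin(as.vector(out), output); return(invisible(out)) }
    return(out)
  }
  streams <- encode_document(doc)
  if (!is.null(dir)) {
    write_container(streams, doc$header_lines, doc$n_records,
                    newline = doc$newline,
                    trailing_newline = doc$trailing_newline,
                    post = post, dir = dir)
    return(invisible(dir))
  }
  out <- write_container(streams, doc$header_lines, doc$n_records,
                         newline = doc$newline,
                         trailing_newline = doc$trailing_newline,
                         post = post)
  t1 <- proc.time()[["elapsed"]]
  per_field <- vapply(streams, function(s)
    stream_size(s) + 10L, numeric(1))   # + framing overhead
  attr(out, "report") <- compression_report(
    original_bytes = length(raw_in),
    encoded_bytes = sum(per_field),
    final_bytes = length(out),
    per_field = per_field,
    encode_seconds = t1 - t0, decode_seconds = NA_real_)
  if (!is.null(output)) { writeBin(as.vector(out), output); return(invisible(out)) }
  out
}

#' Decompress a container back to SAM bytes
#'
#' Exact inverse of [sam_compress()]: the result is byte-identical to the
#' original input.
#'
#' @param input raw vector, `.smz` file path, or per-field directory.
#' @param output optional path to write the SAM text to.
#' @return Raw vector of SAM bytes (invisibly when `output` is given).
#' @export
sam_decompress <- function(input, output = NULL) {
  cont <- read_container(input)
  if (cont$mode == "rawdoc") {
    out <- cont$doc_bytes
  } else {
    dec <- decode_document_streams(cont$streams, cont$n_records)
    doc <- sam_from_columns(dec$columns, dec$opt, cont$header_lines,
                            cont$newline, cont$trailing_newline)
    out <- render_sam(doc)
  }
  if (!is.null(output)) { writeBin(as.vector(out), output); return(invisible(out)) }
  out
}

#' Verify that a container reproduces a SAM file byte-for-byte
#'
#' @param sam original SAM input (raw, path or string).
#' @param container container (raw, path or directory).
#' @return TRUE if the round trip is byte-identical, FALSE otherwise.
#' @export
sam_verify <- function(sam, container) {
  identical(as_sam_bytes(sam), sam_decompress(container))
}
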