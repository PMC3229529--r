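# Loss-free SAM text parsing and rendering.
#
# A parsed document keeps the header lines verbatim, the eleven mandatory
# fields as text columns (never as parsed numbers -- leading zeros and other
# unusual but legal spellings must survive), the optional-field tokens per
# record, and the file's newline convention, so that rendering reproduces the
# input byte-for-byte.

SAM_FIELDS <- c("QNAME", "FLAG", "RNAME", "POS", "MAPQ", "CIGAR",
                "MRNM", "MPOS", "ISIZE", "SEQ", "QUAL")

#' Parse SAM text into a loss-free in-memory document
#'
#' Header lines (starting with `@`) must precede all alignment lines. Each
#' alignment line must carry at least 11 TAB-separated fields; any further
#' tokens are kept as optional `TAG:VTYPE:VALUE` fields in their original
#' order. The newline convention (LF or CRLF) and the presence of a final
#' newline are recorded so that [render_sam()] is an exact inverse. A file
#' mixing LF and CRLF terminators raises a condition of class
#' `samzip_mixed_newlines`.
#'
#' @param raw a raw vector, a file path, or a single character string of SAM
#'   text.
#' @return An object of class `sam_document`.
#' @seealso [render_sam()], [sam_transpose()]
#' @export
parse_sam <- function(raw) {
  raw <- as_sam_bytes(raw)
  if (length(raw) == 0L) {
    return(new_sam_document(character(0), empty_columns(), list(),
                            newline = "LF", trailing_newline = FALSE))
  }
  nl <- which(raw == as.raw(10L))
  crlf <- logical(0)
  if (length(nl) > 0L) {
    prev <- nl - 1L
    crlf <- prev >= 1L & raw[pmax(prev, 1L)] == as.raw(13L)
    crlf[nl == 1L] <- FALSE
  }
  if (length(crlf) > 0L && any(crlf) && !all(crlf))
    stop(structure(class = c("samzip_mixed_newlines", "error", "condition"),
                   list(message = "mixed LF/CRLF line terminators", call = sys.call())))
  newline <- if (length(crlf) > 0L && all(crlf) && length(crlf) > 0L) "CRLF" else "LF"
  terminator <- if (newline == "CRLF") "\r\n" else "\n"
  trailing <- raw[length(raw)] == as.raw(10L)

  txt <- rawToChar(raw)
  lines <- strsplit(txt, terminator, fixed = TRUE, useBytes = TRUE)[[1L]]
  # strsplit drops a final empty piece; a terminated last line is already
  # accounted for by `trailing`
  is_header <- startsWith(lines, "@")
  n_lines <- length(lines)
  first_aln <- match(FALSE, is_header, nomatch = n_lines + 1L)
  if (first_aln <= n_lines && any(is_header[first_aln:n_lines]))
    stop_malformed(sprintf(
      "header line after first alignment line (line %d)",
      first_aln - 1L + which(is_header[first_aln:n_lines])[1L]))
  header_lines <- lines[seq_len(first_aln - 1L)]
  aln <- if (first_aln <= n_lines) lines[first_aln:n_lines] else character(0)

  if (length(aln) == 0L) {
    return(new_sam_document(header_lines, empty_columns(), list(),
                            newline = newline, trailing_newline = trailing))
  }
  toks <- strsplit(aln, "\t", fixed = TRUE, useBytes = TRUE)
  lens <- lengths(toks)
  bad <- which(lens < 11L)
  if (length(bad) > 0L)
    stop_malformed(sprintf("alignment line %d has %d fields (11 required)",
                           first_aln - 1L + bad[1L], lens[bad[1L]]))
  flat <- unlist(toks, use.names = FALSE)
  starts <- cumsum(c(1L, lens[-length(lens)]))
  columns <- stats::setNames(
    lapply(seq_len(11L), function(j) flat[starts + j - 1L]), SAM_FIELDS)
  opt <- mapply(function(s, l) if (l > 11L) flat[(s + 11L):(s + l - 1L)] else character(0),
                starts, lens, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  bad_tag <- !vapply(opt, function(x)
    all(nchar(x) >= 5L & substr(x, 3L, 3L) == ":" & substr(x, 5L, 5L) == ":"),
    logical(1))
  if (any(bad_tag))
    stop_malformed(sprintf("malformed optional tag on alignment line %d",
                           first_aln - 1L + which(bad_tag)[1L]))
  new_sam_document(header_lines, columns, opt,
                   newline = newline, trailing_newline = trailing)
}

#' Render a parsed document back to SAM bytes
#'
#' Exact inverse of [parse_sam()]: header lines verbatim, TAB-joined fields,
#' the recorded newline convention, and the recorded presence or absence of a
#' final newline.
#'
#' @param doc a `sam_document`.
#' @return Raw vector of SAM text.
#' @export
render_sam <- function(doc) {
  stopifnot(inherits(doc, "sam_document"))
  for (col in doc$columns)
    if (any(grepl("\t", col, fixed = TRUE)) || any(grepl("\n", col, fixed = TRUE)))
      stop_malformed("field value contains TAB or newline")
  lines <- doc$header_lines
  if (doc$n_records > 0L) {
    rec <- do.call(paste, c(unname(doc$columns), list(sep = "\t")))
    has_opt <- lengths(doc$opt) > 0L
    if (any(has_opt)) {
      extra <- vapply(doc$opt[has_opt], paste, character(1), collapse = "\t")
      rec[has_opt] <- paste(rec[has_opt], extra, sep = "\t")
    }
    lines <- c(lines, rec)
  }
  if (length(lines) == 0L) return(raw(0))
  terminator <- if (doc$newline == "CRLF") "\r\n" else "\n"
  txt <- paste(lines, collapse = terminator)
  if (doc$trailing_newline) txt <- paste0(txt, terminator)
  charToRaw(txt)
}

#' Split a document into per-field columns
#'
#' Returns the 11 mandatory field columns plus the `OPT` column of
#' optional-field token groups -- the unit on which the field codecs operate.
#' Each field can be encoded independently of the others.
#'
#' @param doc a `sam_document`.
#' @return Named list of 12 columns, each of length `n_records`.
#' @export
sam_transpose <- function(doc) {
  stopifnot(inherits(doc, "sam_document"))
  c(doc$columns, list(OPT = doc$opt))
}

# Internal constructors --------------------------------------------------------

new_sam_document <- function(header_lines, columns, opt, newline, trailing_newline) {
  n <- length(columns[[1L]])
  if (length(opt) == 0L) opt <- rep(list(character(0)), n)
  structure(list(header_lines = header_lines,
                 columns = columns,
                 opt = opt,
                 n_records = n,
                 newline = newline,
                 trailing_newline = trailing_newline),
            class = "sam_document")
}

empty_columns <- function() {
  stats::setNames(rep(list(character(0)), 11L), SAM_FIELDS)
}

# Rebuild a document from transposed columns (inverse of sam_transpose)
sam_from_columns <- function(columns, opt, header_lines, newline, trailing_newline) {
  new_sam_document(header_lines, columns[SAM_FIELDS], opt,
                   newline = newline, trailing_newline = trailing_newline)
}

as_sam_bytes <- function(x) {
  if (is.raw(x)) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (file.exists(x)) return(readBin(x, "raw", file.size(x)))
    return(charToRaw(x))
  }
  stop("input must be a raw vector, a file path, or a single string")
}

#' @export
print.sam_document <- function(x, ...) {
  cat(sprintf("<sam_document: %d header line(s), %d record(s), %s%s>\n",
              length(x$header_lines), x$n_records, x$newline,
              if (x$trailing_newline) "" else ", no final newline"))
  invisible(x)
}
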