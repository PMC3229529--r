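fid <- samzip:::FIELD_IDS
codec <- samzip:::CODEC

test_that("QNAME columns sharing a template avoid fallback and round-trip", {
  col <- c("r001", "r002", "r002", "r003", "r003", "r004")
  s <- encode_qname(col)
  expect_false(s$fallback)
  expect_identical(s$codec_id, codec[["QNAME_TEMPLATE"]])
  expect_identical(decode_field(s), col)

  # constant names: zero slots, empty payload
  s2 <- encode_qname(c("x", "x", "x"))
  expect_false(s2$fallback)
  expect_identical(length(s2$payload), 0L)
  expect_identical(decode_field(s2), c("x", "x", "x"))

  # divergent token structure forces raw fallback
  s3 <- encode_qname(c("read_7_A", "read_9_B"))
  expect_true(s3$fallback)
  expect_identical(decode_field(s3), c("read_7_A", "read_9_B"))

  # leading-zero widths, multi-slot names, and huge digit runs all survive
  cases <- list(
    c("r001", "r010", "r100"),
    c("HWI:1:23:456", "HWI:1:24:457", "HWI:1:25:458"),
    sprintf("q%030d", 1:3),                 # > 15 digits -> text slot
    c("a01", "a001"),                       # differing zero-padded widths
    character(0),
    "solo123")
  for (col in cases) expect_identical(decode_field(encode_qname(col)), col)
})

test_that("token RLE compresses runs and falls back on all-distinct columns", {
  col <- c("0", "0", "0", "16", "16")
  s <- encode_rle_text(col, fid[["FLAG"]])
  expect_false(s$fallback)
  expect_identical(decode_field(s), col)

  distinct <- as.character(sample.int(1e6, 200))
  s2 <- encode_rle_text(distinct, fid[["CIGAR"]])
  expect_true(s2$fallback)
  expect_identical(decode_field(s2), distinct)
  # expansion guard: never larger than raw + header bound
  raw_size <- sum(nchar(distinct)) + length(distinct) - 1
  expect_lte(samzip:::stream_size(s2), raw_size + 16)
})

test_that("QUAL run-length coding works character-wise within records", {
  col <- c("IIIIIIII", "IIIHHHGG")
  s <- encode_qual(col)
  expect_identical(s$codec_id, codec[["QUAL_RLE"]])
  expect_identical(decode_field(s), col)
  # a single 8-char run collapses to one (count, value) pair
  one <- encode_qual("IIIIIIII")
  h <- varint_decode(one$payload, 2)
  expect_identical(h$values, c(1, 8))   # n_runs = 1, count = 8
  # high-entropy quality strings fall back
  set.seed(4)
  noisy <- vapply(1:50, function(i)
    paste(sample(strsplit(rawToChar(as.raw(33:73)), "")[[1]], 20, TRUE),
          collapse = ""), character(1))
  s2 <- encode_qual(noisy)
  expect_true(s2$fallback)
  expect_identical(decode_field(s2), noisy)
})

test_that("POS uses delta + RLE and guards non-canonical spellings", {
  col <- c("7", "7", "9", "9", "9", "16")
  s <- encode_pos(col)
  expect_false(s$fallback)
  expect_identical(s$codec_id, codec[["INT_DELTA_RLE"]])
  expect_identical(decode_field(s), col)

  s1 <- encode_pos("100")
  expect_identical(decode_field(s1), "100")

  lead0 <- c("007", "008")
  s2 <- encode_pos(lead0)
  expect_true(s2$fallback)
  expect_identical(decode_field(s2), lead0)

  huge <- c("1", "99999999999999999999")   # 20 digits: beyond exact doubles
  s3 <- encode_pos(huge)
  expect_true(s3$fallback)
  expect_identical(decode_field(s3), huge)
})

test_that("MRNM bitmaps encode =/* at one bit per record", {
  col <- c("=", "=", "*", "=")
  s <- encode_mrnm(col)
  expect_identical(s$codec_id, codec[["MRNM_BITMAP"]])
  expect_identical(s$payload, as.raw(0x20))   # bits 0010 padded
  expect_identical(decode_field(s), col)

  mixed <- c("chr2", "chr2", "=")
  s2 <- encode_mrnm(mixed)
  expect_identical(s2$codec_id, codec[["RLE_TOKEN"]])
  expect_identical(decode_field(s2), mixed)

  s3 <- encode_mrnm(character(0))
  expect_identical(s3$payload, raw(0))
  expect_identical(decode_field(s3), character(0))
})

test_that("ISIZE collapses to a constant-zero stream when possible", {
  s <- encode_isize(c("0", "0", "0"))
  expect_identical(s$codec_id, codec[["CONST_ZERO"]])
  expect_identical(length(s$payload), 0L)
  expect_identical(decode_field(s), c("0", "0", "0"))

  signed <- c("0", "-120", "120")
  s2 <- encode_isize(signed)
  expect_false(s2$fallback)
  expect_identical(decode_field(s2), signed)

  s3 <- encode_isize(character(0))
  expect_identical(s3$codec_id, codec[["CONST_ZERO"]])
  expect_identical(decode_field(s3), character(0))
})

test_that("SEQ packs 2 bits per base with an N sidecar", {
  r <- encode_seq(c("ACGT", "TTAG"))
  expect_identical(r$base$codec_id, codec[["SEQ_2BIT"]])
  expect_length(r$base$payload, 2L)          # ceil(8/4)
  expect_identical(varint_decode(r$base$params, 2)$values, c(4, 4))
  expect_identical(varint_decode(r$sidecar$payload, 1)$values, 0)
  expect_identical(decode_field(r$base, sidecar = r$sidecar), c("ACGT", "TTAG"))

  col_n <- c("ANGTAAAA", "ACGTACGT")         # one N: record 0, position 1
  rn <- encode_seq(col_n)
  expect_false(rn$base$fallback)
  side <- varint_decode(rn$sidecar$payload, 3)$values
  expect_identical(side, c(1, 0, 1))
  expect_identical(decode_field(rn$base, sidecar = rn$sidecar), col_n)
  # tiny columns where packing cannot pay for its framing stay raw
  tiny <- encode_seq("ANGT")
  expect_identical(decode_field(tiny$base, sidecar = tiny$sidecar), "ANGT")

  star <- encode_seq("*")
  expect_true(star$base$fallback)
  expect_identical(decode_field(star$base, sidecar = star$sidecar), "*")

  # N-heavy and N-only records
  hard <- c("NNNN", "ANNA", "NACGTN")
  rh <- encode_seq(hard)
  expect_identical(decode_field(rh$base, sidecar = rh$sidecar), hard)
})

test_that("tag streams Huffman-code TAG/VTYPE and keep values verbatim", {
  opt <- rep(list("NM:i:0"), 4)
  s <- encode_tags(opt)
  expect_identical(s$codec_id, codec[["TAGS_HUFFMAN"]])
  expect_identical(decode_field(s), opt)

  none <- rep(list(character(0)), 3)
  s2 <- encode_tags(none)
  expect_identical(decode_field(s2), none)

  two <- list(c("NM:i:1", "MD:Z:5A0"))
  s3 <- encode_tags(two)
  expect_identical(decode_field(s3), two)    # order preserved

  ragged <- list(character(0), c("NM:i:3", "MD:Z:10", "AS:i:-5"),
                 "XX:Z:", c("NM:i:0"))
  s4 <- encode_tags(ragged)
  expect_identical(decode_field(s4), ragged)
})

test_that("every field codec round-trips adversarial random columns", {
  set.seed(77)
  rand_txt <- function(n, max_len = 12) {
    alphabet <- strsplit("abcXYZ0123456789=*:_-", "")[[1]]
    vapply(seq_len(n), function(i)
      paste(sample(alphabet, sample.int(max_len, 1), TRUE), collapse = ""),
      character(1))
  }
  for (i in 1:20) {
    n <- sample(0:50, 1)
    col <- rand_txt(n)
    expect_identical(decode_field(encode_qname(col)), col)
    expect_identical(decode_field(encode_rle_text(col, fid[["CIGAR"]])), col)
    expect_identical(decode_field(encode_pos(col)), col)
    expect_identical(decode_field(encode_isize(col)), col)
    expect_identical(decode_field(encode_mrnm(col)), col)
    expect_identical(decode_field(encode_qual(col)), col)
    sq <- encode_seq(col)
    expect_identical(decode_field(sq$base, sidecar = sq$sidecar), col)
  }
})

test_that("stream sets disagreeing on record count are rejected", {
  doc <- parse_sam(example_sam_bytes())
  streams <- encode_document(doc)
  expect_error(decode_document_streams(streams, doc$n_records + 1L),
               class = "samzip_corrupt")
  dec <- decode_document_streams(streams, doc$n_records)
  expect_identical(dec$columns$POS, doc$columns$POS)
  expect_identical(dec$opt, doc$opt)
})
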