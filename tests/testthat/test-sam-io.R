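test_that("the worked example parses into the expected records", {
  doc <- parse_sam(example_sam_bytes())
  expect_s3_class(doc, "sam_document")
  expect_identical(doc$n_records, 6L)
  expect_length(doc$header_lines, 2L)
  expect_identical(doc$columns$QNAME,
                   c("r001", "r002", "r002", "r003", "r003", "r004"))
  expect_identical(doc$columns$QNAME[1], "r001")
  expect_identical(doc$columns$POS, c("7", "7", "9", "9", "9", "16"))
  expect_identical(doc$columns$RNAME, rep("ref", 6))
  expect_identical(doc$opt[[3]], "NM:i:1")
  expect_identical(doc$opt[[1]], character(0))
})

test_that("a single alignment line splits into 11 mandatory fields", {
  line <- "q1\t0\tchr1\t10\t30\t5M\t=\t20\t0\tACGTA\tIIIII"
  doc <- parse_sam(charToRaw(line))
  expect_identical(doc$n_records, 1L)
  expect_identical(doc$columns$SEQ, "ACGTA")
  expect_identical(doc$opt[[1]], character(0))
  expect_false(doc$trailing_newline)
  expect_identical(render_sam(doc), charToRaw(line))
})

test_that("empty input yields an empty document", {
  doc <- parse_sam(raw(0))
  expect_identical(doc$n_records, 0L)
  expect_length(doc$header_lines, 0L)
  expect_identical(render_sam(doc), raw(0))
})

test_that("render after parse is the identity on randomized documents", {
  for (seed in 1:25) {
    x <- sam_generate(random_gen_params(seed))
    expect_identical(render_sam(parse_sam(x)), x)
  }
  # CRLF and missing final newline variants
  x <- charToRaw("@HD\tVN:1.4\r\nq1\t0\tc\t1\t0\t1M\t=\t1\t0\tA\tI\r\n")
  doc <- parse_sam(x)
  expect_identical(doc$newline, "CRLF")
  expect_identical(render_sam(doc), x)
  x2 <- charToRaw("q1\t0\tc\t1\t0\t1M\t=\t1\t0\tA\tI\nq2\t0\tc\t1\t0\t1M\t=\t1\t0\tA\tI")
  expect_identical(render_sam(parse_sam(x2)), x2)
})

test_that("malformed input raises informative errors", {
  expect_error(parse_sam(charToRaw("q1\t0\tchr1\t10\n")),
               "line 1", class = "samzip_malformed")
  expect_error(parse_sam(charToRaw("@HD\tVN:1.4\nq1\t0\tc\t1\t0\t1M\t=\t1\t0\tA\n")),
               "line 2", class = "samzip_malformed")
  expect_error(
    parse_sam(charToRaw("q1\t0\tc\t1\t0\t1M\t=\t1\t0\tA\tI\n@SQ\tSN:c\n")),
    "header line after", class = "samzip_malformed")
  expect_error(
    parse_sam(charToRaw("q1\t0\tc\t1\t0\t1M\t=\t1\t0\tA\tI\tNMi0\n")),
    "tag", class = "samzip_malformed")
  mixed <- charToRaw("@HD\tVN:1.4\nq1\t0\tc\t1\t0\t1M\t=\t1\t0\tA\tI\r\n")
  expect_error(parse_sam(mixed), class = "samzip_mixed_newlines")
})

test_that("transpose yields 12 order-preserving columns", {
  doc <- parse_sam(example_sam_bytes())
  cols <- sam_transpose(doc)
  expect_length(cols, 12L)
  expect_identical(names(cols)[12], "OPT")
  expect_identical(cols$RNAME, rep("ref", 6))
  expect_identical(cols$FLAG, c("163", "0", "0", "0", "16", "16"))
  # reassembly reproduces the record sequence
  doc2 <- samzip:::sam_from_columns(cols[1:11], cols$OPT, doc$header_lines,
                                    doc$newline, doc$trailing_newline)
  expect_identical(render_sam(doc2), example_sam_bytes())
  # zero-record document
  empty <- parse_sam(charToRaw("@HD\tVN:1.4\n"))
  cols0 <- sam_transpose(empty)
  expect_length(cols0, 12L)
  expect_true(all(lengths(cols0) == 0L))
})

test_that("three synthetic records project FLAG by direct copy", {
  x <- paste(
    "a\t0\tc\t1\t0\t1M\t=\t1\t0\tA\tI",
    "b\t0\tc\t2\t0\t1M\t=\t2\t0\tA\tI",
    "c\t16\tc\t3\t0\t1M\t=\t3\t0\tA\tI", sep = "\n")
  cols <- sam_transpose(parse_sam(charToRaw(x)))
  expect_identical(cols$FLAG, c("0", "0", "16"))
})

test_that("rendering rejects fields containing separator bytes", {
  doc <- parse_sam(example_sam_bytes())
  doc$columns$RNAME[2] <- "bad\tname"
  expect_error(render_sam(doc), class = "samzip_malformed")
})
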