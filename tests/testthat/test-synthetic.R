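test_that("generation is deterministic in the seed", {
  a <- sam_generate(sam_gen_params(n_records = 200, seed = 42))
  b <- sam_generate(sam_gen_params(n_records = 200, seed = 42))
  expect_identical(a, b)
  c_ <- sam_generate(sam_gen_params(n_records = 200, seed = 43))
  expect_false(identical(a, c_))
  # generation must not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(sam_generate(sam_gen_params(n_records = 5, seed = 9)))
  expect_identical(runif(1), before)
})

test_that("zero records produce a header-only file", {
  x <- sam_generate(sam_gen_params(n_records = 0, seed = 1))
  doc <- parse_sam(x)
  expect_identical(doc$n_records, 0L)
  expect_gt(length(doc$header_lines), 0L)
  expect_identical(sam_decompress(sam_compress(x)), x)
})

test_that("generated files parse and expose the intended statistics", {
  p <- sam_gen_params(n_records = 500, seed = 7)
  doc <- parse_sam(sam_generate(p))
  cols <- sam_transpose(doc)
  expect_identical(doc$n_records, 500L)
  # POS non-decreasing within each reference block
  for (r in unique(cols$RNAME)) {
    pos <- as.integer(cols$POS[cols$RNAME == r])
    expect_true(all(diff(pos) >= 0))
  }
  expect_true(all(cols$ISIZE == "0"))
  expect_true(all(cols$MRNM %in% c("=", "*")))
  expect_true(all(grepl("^[ACGTN]+$", cols$SEQ)))
  expect_true(all(nchar(cols$SEQ) == p$read_len))
})

test_that("the all-zero ISIZE column encodes to a zero-byte constant stream", {
  x <- sam_generate(sam_gen_params(n_records = 100, seed = 3))
  cont <- read_container(sam_compress(x))
  isize <- cont$streams$isize
  expect_identical(isize$codec_id, samzip:::CODEC[["CONST_ZERO"]])
  expect_identical(length(isize$payload), 0L)
})

test_that("adversarial fixtures force the intended fallback paths", {
  n <- 120
  w <- sam_generate_adversarial("no-repeats", n = n, seed = 5)
  cont <- read_container(sam_compress(w))
  rle_fields <- c("flag", "rname", "mpos", "qual", "mrnm", "cigar")
  for (f in rle_fields) expect_true(cont$streams[[f]]$fallback)
  expect_lte(length(sam_compress(w, post = "none")), length(w) * 1.01)
  expect_identical(sam_decompress(sam_compress(w)), w)

  s <- sam_generate_adversarial("non-ACGTN-seq", n = 50, seed = 5)
  cont2 <- read_container(sam_compress(s))
  expect_true(cont2$streams$seq$fallback)
  expect_identical(sam_decompress(sam_compress(s)), s)

  q <- sam_generate_adversarial("divergent-qnames", n = 50, seed = 5)
  cont3 <- read_container(sam_compress(q))
  expect_true(cont3$streams$qname$fallback)
  expect_identical(sam_decompress(sam_compress(q)), q)

  z <- sam_generate_adversarial("leading-zero-pos", n = 50, seed = 5)
  cont4 <- read_container(sam_compress(z))
  expect_true(cont4$streams$pos$fallback)
  expect_identical(sam_decompress(sam_compress(z)), z)
})

test_that("presets are reproducible and well-formed", {
  a <- sam_generate_preset("paperlike", n_records = 100, seed = 2)
  expect_identical(a, sam_generate_preset("paperlike", n_records = 100, seed = 2))
  b <- sam_generate_preset("worstcase", n_records = 100, seed = 2)
  expect_identical(parse_sam(b)$n_records, 100L)
})
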