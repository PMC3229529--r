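test_that("run-length encoding groups adjacent repeats and inverts exactly", {
  r <- rle_encode(c("0", "0", "0", "16"))
  expect_identical(r$values, c("0", "16"))
  expect_identical(as.integer(r$counts), c(3L, 1L))
  expect_identical(rle_encode(character(0))$counts, integer(0))
  worst <- rle_encode(c("a", "b", "c"))
  expect_identical(as.integer(worst$counts), c(1L, 1L, 1L))
  expect_identical(rle_decode(list(values = "I", counts = 5L)), rep("I", 5))
  set.seed(5)
  tokens <- sample(c("x", "y", "z"), 1000, replace = TRUE)
  r <- rle_encode(tokens)
  expect_true(all(r$values[-1] != r$values[-length(r$values)]))
  expect_identical(sum(r$counts), 1000L)
  expect_identical(rle_decode(r), tokens)
  expect_error(rle_decode(list(values = "a", counts = 0L)), class = "samzip_corrupt")
})

test_that("delta encoding stores first value plus differences", {
  d <- delta_encode(c(7, 7, 9, 9, 9, 16))
  expect_identical(d$first, 7)
  expect_identical(d$diffs, c(0, 2, 0, 0, 7))
  expect_identical(delta_decode(7, c(0, 2, 0, 0, 7)), c(7, 7, 9, 9, 9, 16))
  expect_identical(delta_encode(5), list(first = 5, diffs = numeric(0)))
  expect_identical(delta_decode(5, numeric(0)), 5)
  expect_identical(delta_encode(c(10, 4))$diffs, -6)
  expect_identical(delta_decode(10, -6), c(10, 4))
  expect_identical(delta_decode(delta_encode(numeric(0))$first, numeric(0)),
                   numeric(0))
})

test_that("Huffman coding handles uniform, skewed and degenerate alphabets", {
  # uniform power-of-two alphabet degenerates to plain binary
  tab <- huffman_build(c(A = 5, C = 5, G = 5, T = 5))
  expect_identical(tab$lengths, rep(2L, 4))
  toks <- rep(c("A", "C", "G", "T"), 2)
  bs <- huffman_encode(toks, tab)
  expect_identical(bs$bit_count, 16L)
  expect_identical(huffman_decode(bs, tab, 8), toks)

  expect_identical(huffman_table_cost(c(A = 4, B = 2, C = 1, D = 1)), 14)

  single <- huffman_build(c(X = 100))
  expect_identical(single$lengths, 1L)
  bs1 <- huffman_encode(rep("X", 10), single)
  expect_identical(bs1$bit_count, 10L)
  expect_identical(huffman_decode(bs1, single, 10), rep("X", 10))

  expect_identical(huffman_encode(character(0), tab)$bit_count, 0L)
  expect_error(huffman_build(numeric(0)))
  expect_error(huffman_encode("Z", tab))
  short <- huffman_encode(c("A", "C"), tab)
  expect_error(huffman_decode(short, tab, 3), class = "samzip_corrupt")
})

test_that("Huffman codes are prefix-free and within one bit of entropy", {
  set.seed(21)
  for (i in 1:25) {
    k <- sample(2:12, 1)
    freqs <- stats::setNames(sample(1:50, k, replace = TRUE),
                             paste0("s", seq_len(k)))
    tab <- huffman_build(freqs)
    # prefix-freeness
    for (a in seq_along(tab$codes))
      for (b in seq_along(tab$codes))
        if (a != b) expect_false(startsWith(tab$codes[b], tab$codes[a]))
    # Kraft
    expect_lte(sum(2^(-tab$lengths)), 1 + 1e-12)
    # mean code length in [H, H + 1)
    cnt <- as.double(freqs)[match(tab$symbols, names(freqs))]
    mean_len <- sum(tab$lengths * cnt) / sum(cnt)
    H <- empirical_entropy(cnt)
    expect_gte(mean_len, H - 1e-9)
    expect_lt(mean_len, H + 1)
    # round trip
    toks <- sample(names(freqs), 300, replace = TRUE)
    expect_identical(huffman_decode(huffman_encode(toks, tab), tab, 300), toks)
  }
})

test_that("canonical tables rebuild from code lengths alone", {
  freqs <- c(NM = 40, MD = 10, AS = 3, XS = 3)
  tab <- huffman_build(freqs)
  rebuilt <- huffman_canonical(tab$symbols, tab$lengths)
  expect_identical(rebuilt, tab)
})

test_that("2-bit packing uses the fixed ACGT mapping MSB-first", {
  expect_identical(pack_2bit("ACGT")$bytes, as.raw(0x1B))
  expect_identical(pack_2bit("AAAA")$bytes, as.raw(0x00))
  expect_identical(pack_2bit("")$bytes, raw(0))
  expect_error(pack_2bit("ACGN"))
  set.seed(31)
  for (n in c(1, 3, 4, 5, 17, 1000)) {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    bs <- pack_2bit(s)
    expect_identical(bs$bit_count, 2L * as.integer(n))
    expect_length(bs$bytes, ceiling(n / 4))
    expect_identical(unpack_2bit(bs, n), s)
  }
})
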