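# Shared fixtures and independent oracles.

example_sam_path <- function() {
  system.file("extdata", "example.sam", package = "samzip", mustWork = TRUE)
}

example_sam_bytes <- function() {
  p <- example_sam_path()
  readBin(p, "raw", file.size(p))
}

# --- Brute-force optimal prefix-code oracle ----------------------------------
# Enumerates every sorted code-length multiset over k symbols that satisfies
# Kraft equality (every optimal prefix code corresponds to a complete binary
# tree), then matches the largest counts to the shortest lengths. Independent
# of the Huffman implementation.

valid_length_multisets <- function(k) {
  if (k == 1L) return(matrix(1L, nrow = 1L))
  maxlen <- k - 1L
  grid <- as.matrix(expand.grid(rep(list(seq_len(maxlen)), k)))
  kraft <- rowSums(2^(-grid))
  g <- grid[abs(kraft - 1) < 1e-12, , drop = FALSE]
  g <- t(apply(g, 1L, sort))
  unique(g)
}

optimal_prefix_cost <- function(counts, length_sets = NULL) {
  k <- length(counts)
  if (k == 1L) return(counts[[1L]])     # degenerate: 1-bit code
  if (is.null(length_sets)) length_sets <- valid_length_multisets(k)
  sc <- sort(as.double(counts), decreasing = TRUE)
  min(apply(length_sets, 1L, function(l) sum(sc * l)))
}

huffman_table_cost <- function(freqs) {
  tab <- huffman_build(freqs)
  sum(tab$lengths * as.double(freqs)[match(tab$symbols, names(freqs))])
}

# empirical Shannon entropy in bits/symbol
empirical_entropy <- function(counts) {
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# all non-decreasing count tuples of length k with entries in 1..maxc
count_multisets <- function(k, maxc) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(maxc)), k)))
  keep <- rowSums(grid[, -1L, drop = FALSE] >= grid[, -k, drop = FALSE]) == k - 1L
  grid[keep, , drop = FALSE]
}

# a small randomized document for round-trip properties
random_gen_params <- function(seed) {
  set.seed(seed)
  sam_gen_params(
    n_records = sample(0:30, 1),
    seed = seed,
    sorted_pos = sample(c(TRUE, FALSE), 1),
    pos_gap_mean = sample(c(1, 5, 50), 1),
    read_len = sample(c(8L, 36L), 1),
    n_rate = sample(c(0, 0.01, 0.3), 1),
    qual_run_mean = sample(c(1, 4), 1),
    mrnm_eq_frac = runif(1),
    isize_mode = sample(c("zero", "mixed"), 1),
    tag_nm_prob = runif(1),
    tag_md_prob = runif(1))
}

adversarial_kinds <- c("no-repeats", "mixed-newlines-rejected",
                       "non-ACGTN-seq", "leading-zero-pos",
                       "divergent-qnames")
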