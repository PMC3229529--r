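# Deterministic synthetic SAM generator.
#
# Emulates the field statistics that the codecs exploit in real
# coordinate-sorted short-read data: read names sharing one template,
# a few reference names in long runs, non-decreasing positions with small
# geometric gaps, a small palette of FLAG/MAPQ values, mostly-'=' mate
# reference names, all-zero insert sizes, ACGT sequence with rare N, and
# quality strings built from runs. The "worstcase" preset negates all of
# this: no value repeats its neighbour, so every run-length codec must take
# its raw fallback.

#' Generator parameters
#'
#' Defaults describe a "paperlike" coordinate-sorted paired-end file. All
#' randomness is controlled by `seed`: the same parameters always produce the
#' same bytes.
#'
#' @param n_records number of alignment records.
#' @param seed integer RNG seed.
#' @param qname_prefix,qname_width read-name template: names are
#'   `prefix` followed by a zero-padded counter of this width.
#' @param references named numeric vector of reference-name weights.
#' @param ref_len reference length written in the `@SQ` header lines.
#' @param sorted_pos whether POS is non-decreasing within each reference.
#' @param pos_gap_mean mean geometric gap between successive positions.
#' @param flags named weights over FLAG values.
#' @param mapqs named weights over MAPQ values.
#' @param read_len read length (SEQ and QUAL width).
#' @param n_rate per-base probability of an N in SEQ.
#' @param qual_alphabet characters qualities are drawn from.
#' @param qual_run_mean mean quality run length.
#' @param mrnm_eq_frac fraction of records with MRNM `=` (the rest are `*`).
#' @param isize_mode `"zero"` (constant 0) or `"mixed"` (signed values).
#' @param tag_nm_prob probability a record carries an `NM:i:` tag.
#' @param tag_md_prob probability a record carries an `MD:Z:` tag.
#' @return List of class `sam_gen_params`.
#' @export
sam_gen_params <- function(n_records = 1000L,
                           seed = 1L,
                           qname_prefix = "r",
                           qname_width = 6L,
                           references = c(chr1 = 0.7, chr2 = 0.3),
                           ref_len = 100000L,
                           sorted_pos = TRUE,
                           pos_gap_mean = 20,
                           flags = c(`99` = 0.3, `147` = 0.3, `83` = 0.15,
                                     `163` = 0.15, `0` = 0.05, `16` = 0.05),
                           mapqs = c(`37` = 0.7, `60` = 0.2, `0` = 0.1),
                           read_len = 36L,
                           n_rate = 0.002,
                           qual_alphabet = c("I", "H", "G", "F", "E", "D", "C", "B"),
                           qual_run_mean = 4,
                           mrnm_eq_frac = 0.9,
                           isize_mode = c("zero", "mixed"),
                           tag_nm_prob = 0.95,
                           tag_md_prob = 0.3) {
  isize_mode <- match.arg(isize_mode)
  stopifnot(n_records >= 0, pos_gap_mean > 0, read_len >= 1,
            n_rate >= 0, n_rate <= 1, qual_run_mean >= 1,
            mrnm_eq_frac >= 0, mrnm_eq_frac <= 1,
            abs(sum(references) - 1) < 1e-8,
            abs(sum(flags) - 1) < 1e-8, abs(sum(mapqs) - 1) < 1e-8)
  structure(as.list(environment()), class = "sam_gen_params")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

run_chars <- function(total, alphabet, run_mean) {
  # sample geometric-length runs until `total` characters are available
  out <- character(0)
  got <- 0L
  while (got < total) {
    k <- max(50L, ceiling((total - got) / run_mean))
    lens <- 1L + stats::rgeom(k, 1 / run_mean)
    vals <- sample(alphabet, k, replace = TRUE)
    out <- c(out, rep(vals, lens))
    got <- length(out)
  }
  out[seq_len(total)]
}

#' Generate a synthetic SAM file
#'
#' @param params a [sam_gen_params()] object.
#' @return Raw vector of well-formed SAM text that always round-trips through
#'   the codec.
#' @export
sam_generate <- function(params = sam_gen_params()) {
  stopifnot(inherits(params, "sam_gen_params"))
  p <- params
  with_seed(p$seed, {
    refs <- names(p$references)
    header <- c("@HD\tVN:1.4\tSO:coordinate",
                sprintf("@SQ\tSN:%s\tLN:%d", refs, p$ref_len))
    n <- as.integer(p$n_records)
    if (n == 0L)
      return(charToRaw(paste0(paste(header, collapse = "\n"), "\n")))

    qname <- sprintf(paste0(p$qname_prefix, "%0", p$qname_width, "d"), seq_len(n))
    nref <- tabulate(sample.int(length(refs), n, replace = TRUE,
                                prob = p$references), nbins = length(refs))
    rname <- rep(refs, nref)
    pos <- unlist(lapply(nref, function(k) {
      if (k <= 0L) return(integer(0))
      if (p$sorted_pos) 1L + cumsum(stats::rgeom(k, 1 / (p$pos_gap_mean + 1)))
      else sample.int(p$ref_len, k, replace = TRUE)
    }), use.names = FALSE)
    flag <- sample(names(p$flags), n, replace = TRUE, prob = p$flags)
    mapq <- sample(names(p$mapqs), n, replace = TRUE, prob = p$mapqs)
    cigar <- sample(c(sprintf("%dM", p$read_len),
                      sprintf("4S%dM", p$read_len - 4L),
                      sprintf("%dM1I%dM", p$read_len %/% 2L,
                              p$read_len - p$read_len %/% 2L - 1L)),
                    n, replace = TRUE, prob = c(0.9, 0.06, 0.04))
    mrnm_eq <- stats::runif(n) < p$mrnm_eq_frac
    mrnm <- ifelse(mrnm_eq, "=", "*")
    mpos <- ifelse(mrnm_eq, as.character(pos + sample(50:250, n, replace = TRUE)), "0")
    isize <- if (p$isize_mode == "zero") rep("0", n) else
      as.character(ifelse(mrnm_eq, sample(c(-400:-100, 100:400), n, replace = TRUE), 0L))
    base_mat <- matrix(sample(c("A", "C", "G", "T"), n * p$read_len, replace = TRUE),
                       nrow = p$read_len)
    if (p$n_rate > 0) {
      nmask <- stats::runif(n * p$read_len) < p$n_rate
      base_mat[nmask] <- "N"
    }
    seq <- apply(base_mat, 2L, paste, collapse = "")
    qual_chars <- run_chars(n * p$read_len, p$qual_alphabet, p$qual_run_mean)
    qual <- apply(matrix(qual_chars, nrow = p$read_len), 2L, paste, collapse = "")
    nm <- stats::runif(n) < p$tag_nm_prob
    md <- stats::runif(n) < p$tag_md_prob
    nm_val <- stats::rpois(n, 0.3)
    opt <- lapply(seq_len(n), function(i) {
      c(if (nm[i]) sprintf("NM:i:%d", nm_val[i]),
        if (md[i]) sprintf("MD:Z:%d", p$read_len))
    })
    lines <- paste(qname, flag, rname, pos, mapq, cigar, mrnm, mpos, isize,
                   seq, qual, sep = "\t")
    has_opt <- lengths(opt) > 0L
    if (any(has_opt)) {
      extra <- vapply(opt[has_opt], paste, character(1), collapse = "\t")
      lines[has_opt] <- paste(lines[has_opt], extra, sep = "\t")
    }
    charToRaw(paste0(paste(c(header, lines), collapse = "\n"), "\n"))
  })
}

#' Generate a SAM fixture from a named preset
#'
#' `"paperlike"` is the default coordinate-sorted profile;
#' `"worstcase"` has essentially no repeated values, forcing every
#' run-length codec onto its raw fallback.
#'
#' @param preset `"paperlike"` or `"worstcase"`.
#' @param n_records,seed passed through to the generator.
#' @return Raw vector of SAM bytes.
#' @export
sam_generate_preset <- function(preset = c("paperlike", "worstcase"),
                                n_records = 1000L, seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "paperlike")
    return(sam_generate(sam_gen_params(n_records = n_records, seed = seed)))
  sam_generate_adversarial("no-repeats", n = n_records, seed = seed)
}

#' Generate adversarial fixtures that force the fallback paths
#'
#' @param kind one of `"no-repeats"` (nothing repeats; every RLE codec falls
#'   back), `"mixed-newlines-rejected"` (LF and CRLF mixed in one file, which
#'   the parser rejects and the compressor stores verbatim),
#'   `"non-ACGTN-seq"` (`*` and lowercase sequence), `"leading-zero-pos"`
#'   (zero-padded positions that must not be renumbered), and
#'   `"divergent-qnames"` (no shared read-name template).
#' @param n number of records.
#' @param seed integer RNG seed.
#' @return Raw vector of SAM bytes.
#' @export
sam_generate_adversarial <- function(kind = c("no-repeats",
                                              "mixed-newlines-rejected",
                                              "non-ACGTN-seq",
                                              "leading-zero-pos",
                                              "divergent-qnames"),
                                     n = 100L, seed = 1L) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (kind == "mixed-newlines-rejected") {
    base <- sam_generate(sam_gen_params(n_records = n, seed = seed))
    txt <- rawToChar(base)
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
    terms <- rep_len(c("\n", "\r\n"), length(lines))
    return(charToRaw(paste0(paste0(lines, terms), collapse = "")))
  }
  if (kind == "non-ACGTN-seq") {
    base <- sam_generate(sam_gen_params(n_records = n, seed = seed))
    doc <- parse_sam(base)
    doc$columns$SEQ <- rep_len(c("*", "acgtacgt", "ACGTRYKM"), doc$n_records)
    doc$columns$QUAL <- rep_len("*", doc$n_records)
    return(render_sam(doc))
  }
  if (kind == "leading-zero-pos") {
    base <- sam_generate(sam_gen_params(n_records = n, seed = seed))
    doc <- parse_sam(base)
    doc$columns$POS <- sprintf("%08d", as.integer(doc$columns$POS))
    return(render_sam(doc))
  }
  with_seed(seed, {
    header <- "@HD\tVN:1.4"
    rand_str <- function(k, alphabet, len) {
      vapply(seq_len(k), function(i)
        paste(sample(alphabet, len, replace = TRUE), collapse = ""), character(1))
    }
    letters_up <- c(letters, LETTERS)
    if (kind == "divergent-qnames") {
      p <- sam_gen_params(n_records = n, seed = seed + 1L)
      base <- sam_generate(p)
      doc <- parse_sam(base)
      doc$columns$QNAME <- paste0(rand_str(n, letters_up, 4L), "_",
                                  sample.int(10000L, n, replace = TRUE), "_",
                                  rand_str(n, letters_up, 3L))
      return(render_sam(doc))
    }
    # no-repeats: adjacent values never equal, positions unsorted
    qname <- paste0(rand_str(n, letters_up, 8L), seq_len(n))
    flag <- as.character(sample.int(65535L, n))
    rname <- paste0(rand_str(n, letters_up, 6L), seq_len(n))
    pos <- as.character(sample.int(2^28, n))
    mapq <- as.character((seq_len(n) * 7L) %% 255L)
    cigar <- paste0(sample(20:80, n, replace = TRUE), "M",
                    sample(1:19, n, replace = TRUE), "S")
    mrnm <- paste0(rand_str(n, letters_up, 5L), seq_len(n))
    mpos <- as.character(sample.int(2^28, n))
    isize <- as.character(sample(c(-(2^20):-1, 1:(2^20)), n))
    seqs <- rand_str(n, c("A", "C", "G", "T"), 40L)
    quals <- rand_str(n, strsplit(rawToChar(as.raw(33:73)), "")[[1L]], 40L)
    lines <- paste(qname, flag, rname, pos, mapq, cigar, mrnm, mpos, isize,
                   seqs, quals, sep = "\t")
    charToRaw(paste0(paste(c(header, lines), collapse = "\n"), "\n"))
  })
}

#' @export
print.sam_gen_params <- function(x, ...) {
  cat(sprintf("<sam_gen_params: n=%d, seed=%d, %s POS, ISIZE %s>\n",
              x$n_records, x$seed,
              if (x$sorted_pos) "sorted" else "unsorted", x$isize_mode))
  invisible(x)
}
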