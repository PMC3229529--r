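---
title: "Field-aware lossless encoding of SAM files: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-aware lossless encoding of SAM files: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samzip)
```

## The problem

A SAM file is tab-delimited text: a header block of `@`-prefixed lines
followed by alignment records of eleven mandatory fields (QNAME, FLAG,
RNAME, POS, MAPQ, CIGAR, MRNM, MPOS, ISIZE, SEQ, QUAL) plus optional
`TAG:VTYPE:VALUE` fields. A general-purpose compressor sees this as one
undifferentiated byte stream. But each column has its own, very regular
statistics: read names share a template and differ only in counters;
coordinate-sorted positions increase by small, frequently repeated steps; a
handful of FLAG and MAPQ values cover almost all records; the mate
reference name is almost always `=` or `*`; insert sizes are often
uniformly zero; sequence is drawn from {A,C,G,T} with rare N; quality
strings contain long single-character runs.

samzip exploits this by *transposing* the file: each field becomes an
independent stream, encoded by a codec matched to its statistics, and the
streams are framed into a checksummed container. A general-purpose
compressor (DEFLATE, bzip2 or LZMA) can then be applied on top; because the
specialized pre-coding has already removed the structure the general
compressor models poorly across interleaved columns, the combination is
smaller than the general compressor alone. The contract throughout is
strict losslessness: `sam_decompress(sam_compress(x))` is byte-identical to
`x` for every input, including pathological ones.

## Per-field codecs

| Field | Codec | Rationale |
|---|---|---|
| QNAME | shared token template + integer slots | names differ only in counters |
| FLAG, RNAME, MAPQ, CIGAR, MPOS | token run-length encoding | few values, long runs |
| POS | delta + run-length over diffs | sorted, small repeated gaps |
| MRNM | 1-bit dictionary (`=`/`*`) | two values dominate |
| ISIZE | constant-zero, else signed delta path | often uniformly zero |
| SEQ | 2 bits/base + N-position sidecar | 4-letter alphabet, rare N |
| QUAL | character-stream run-length encoding | long within-record runs |
| TAGS | canonical Huffman for TAG/VTYPE, values verbatim | tiny alphabets |

**QNAME.** Names are tokenized into alternating non-digit/digit runs. When
every record has the same token structure and identical non-digit tokens,
the non-digit part becomes a template stored once and each digit run
becomes a column of integers, stored as zigzag-folded varint deltas. We
deliberately interpret the "common part" of read names as this token
template rather than a free-form longest common subsequence: an arbitrary
LCS is not uniquely invertible, while a token template is. Digit runs with
constant width (zero-padded counters such as `r001`) carry a width flag and
are re-rendered with that width; runs with inconsistent leading zeros or
more than 15 digits (the exact-double limit) are stored as text for that
slot only.

**POS / ISIZE.** Values are accepted into the integer path only when the
canonical re-rendering of the parsed number reproduces the original text
exactly -- `007` or a 20-digit value falls back to raw. This is the
mechanism that lets the codec parse integers without ever betraying the
byte-exactness contract. ISIZE has three rungs: a zero-byte constant stream
when every value is `0`, the signed delta path, then token RLE, then raw.

**SEQ.** Per-record lengths go in the stream's parameter block, so the
payload is exactly `ceiling(bases/4)` bytes of 2-bit packed ACGT
(`A=00, C=01, G=10, T=11`, most-significant bits first). N positions are
excised and stored in a sidecar stream as (record-index delta,
within-record-position delta) varint pairs. Any record containing a
character outside ACGTN -- `*` placeholders, lowercase, IUPAC ambiguity
codes -- switches the whole column to raw fallback.

**QUAL.** Runs live *inside* strings, so RLE operates on the concatenated
character stream, with per-record lengths in the parameter block; the other
RLE fields treat whole field values as tokens. High-entropy quality columns
(run length near 1) would expand under RLE and take the raw fallback.

**TAGS.** The two-character TAG codes and one-character VTYPE codes come
from small alphabets and are Huffman coded with per-file tables built from
observed frequencies; tables are serialized as canonical code lengths.
VALUE text is unpredictable and kept verbatim with length prefixes. Tag
order within a record is preserved exactly. Tables are built per file
rather than fixed in the package: a static table would be smaller on
conforming files but could not adapt to local tag dialects.

## The fallback ladder and the expansion guard

Every column is encoded down a ladder: specialized codec, then token RLE,
then raw text. A candidate wins only if (a) decoding it reproduces the
column *exactly* (verified at encode time, not assumed), and (b) its stream
is no larger than the raw representation. The raw rung always succeeds, so
the worst case for any column is its raw bytes plus a fixed per-stream
header (under 16 bytes). On input with no repetition at all the container
is therefore never materially larger than the input -- in practice it is
still smaller, because SEQ packing and position deltas survive even when
every run-length codec has fallen back.

Two whole-file guards back this up. Mixed LF/CRLF terminators cannot be
represented by a single newline-convention flag, so such input is stored
verbatim in a raw-document container. And mandatory fields are kept as
*text*, never as parsed numbers, so unusual but legal spellings round-trip
unchanged.

## Container and integrity

A single-file container holds a magic number, version, mode and backend
bytes, then the body (record count, newline flags, verbatim header blob,
and the framed streams), then a CRC-32 of the uncompressed body. Each
stream frame additionally carries a CRC-32 of its payload. The original
design writes one file per field so that an external compressor can be
pointed at the pieces; `sam_compress(dir = ...)` reproduces that workflow
(`qname.smzf`, `flag.smzf`, ..., `header.smzf`), while the single-file
`.smz` form is the command-line default for practicality. Corruption --
bit flips, truncation, wrong magic or version -- raises typed conditions
rather than producing silently wrong output. The checksums are our
addition: verified losslessness needs a mechanism, not just a promise.

Post-compression backends are DEFLATE, bzip2 and LZMA via R's
`memCompress()`. The architecture being reproduced is "specialized
pre-coder + any general-purpose compressor"; proprietary archivers used in
the original evaluation are intentionally not a dependency.

## Serialization conventions

Integers are serialized as LEB128 varints (base-128, little-endian,
continuation bit in the MSB); signed quantities are zigzag-folded first
(0, -1, 1, -2 map to 0, 1, 2, 3). Bit streams are packed most-significant
bit first with zero padding in the final byte. Huffman tables are
canonical -- codes are reconstructable from the (symbol, length) pairs
alone -- with merge ties broken by (weight, creation order) and canonical
assignment ordered by (length, symbol byte order). A single-symbol alphabet
gets a 1-bit code rather than 0 bits, keeping decode framing trivial. Run
lists serialize as a run count followed by parallel blocks of counts,
value lengths and value bytes; the blocked layout vectorizes better than
interleaved pairs and is bit-for-bit inverted by the reader.

## The transmission-time model

Transfer cost over a fixed link is `(size_gb * 1024) / bandwidth` seconds,
with the T1 reference bandwidth of 0.193 MB/s and the 1024 MB/GB
conversion implied by that arithmetic (3.5 GB becomes 3584 MB). The
*online* cost adds compression and decompression time to the effective
transmission time: a slower, stronger compressor can lose end-to-end even
with a smaller payload. `transmission_seconds()` returns the exact value;
tables round to two decimals for display.

## The synthetic generator

No public corpus accompanies the original description of this scheme, so
all tests run on generated data. `sam_gen_params()` defaults describe a
coordinate-sorted paired-end short-read file of the kind the codecs target:
zero-padded read-name counters (`r000001`, width 6), two references in
sorted blocks, positions advancing by geometric gaps (mean 20, so repeated
positions occur), a six-value FLAG palette, read length 36 (typical of
early short-read instruments), N rate 0.002, quality runs of geometric
mean length 4 over an 8-character alphabet, 90% `=` mate references,
all-zero ISIZE, and `NM:i`/`MD:Z` tags. These values were fixed once as a
realistic profile of that era's data; they are generation conditions, not
tuning knobs.

The `worstcase` preset (and the `no-repeats` adversarial kind) negates
every exploitable property: divergent read names, distinct FLAG/RNAME
values, unsorted positions, random CIGAR, named mate references, nonzero
insert sizes, run-free qualities. The remaining adversarial kinds each
target one guard: mixed newlines, non-ACGTN sequence, zero-padded
positions, and template-free read names.

What the generator does *not* emulate: real reference genomes, biologically
consistent CIGAR/SEQ relationships, realistic quality-score correlation
structure, or multi-sample header complexity. Passing tests therefore
demonstrate the codec contracts (exact inversion, fallback safety,
directional compression on data with the assumed statistics), not absolute
compression ratios on any particular real dataset.

## Numerical choices and limitations

- All integer arithmetic runs in doubles, and every integer-coded value is
  bounded by the canonical-rendering check to 15 digits, far inside the
  2^53 exact range.
- The problem sizes used by the test suite and the acceptance script --
  about a thousand randomized documents of up to ~40 records, plus two
  10,000-record preset files -- were chosen to exercise every code path,
  including all fallbacks, at desk scale.
- Encoding is single-threaded. Columns are encoded strictly independently
  (each encoder receives only its own column), so per-field parallelism is
  available in principle, but concurrency is out of scope.
- BAM/BGZF, random access, CRAM-style reference-based sequence coding and
  lossy quality quantization are out of scope.
- The parser enforces header-before-alignments and at least 11 fields per
  record; it does not validate CIGAR/SEQ consistency or coordinates, which
  is deliberate -- validation beyond what round-tripping requires would
  reject files that are perfectly compressible.

## Worked example

```{r example, eval = FALSE}
x <- sam_generate_preset("paperlike", n_records = 10000, seed = 1)
z <- sam_compress(x, post = "deflate")
length(x); length(z)                      # 1225124 -> 224033 bytes
identical(sam_decompress(z), x)           # TRUE
attr(z, "report")$ratio                   # ~5.5
length(memCompress(x, "gzip"))            # 357102: DEFLATE alone does worse
round(transmission_minutes(3.5), 2)       # 309.5 minutes at T1
```
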