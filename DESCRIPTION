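Package: samzip
Title: Field-Aware Lossless Compression of SAM Alignment Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Columnar, field-aware lossless encoding for Sequence
    Alignment/Map (SAM) text files. Alignment records are split into
    per-field streams and each stream is encoded with a codec matched to
    the field's statistics: run-length encoding for FLAG, MAPQ, RNAME,
    CIGAR, MPOS and QUAL, delta plus run-length encoding for sorted POS
    values, template extraction plus integer coding for read names, a
    one-bit code for the mate reference name, two-bit packing for ACGT
    sequence with an N-position sidecar, and canonical Huffman coding for
    optional tag codes. Streams are framed into a checksummed container
    that can be post-compressed with DEFLATE, bzip2 or LZMA, with the
    guarantee that decompression reconstructs the original file
    byte-for-byte. Includes a deterministic synthetic SAM generator, a
    transmission-time model for estimating transfer cost over a fixed
    bandwidth link, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
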