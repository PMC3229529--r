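# Evaluation arithmetic: compression reports and the transmission-time model.
#
# Transfer cost is modelled over a fixed-bandwidth link; the reference figure
# is a T1 line at 1.544 Mbps, i.e. 0.193 MB/s. File sizes quoted in GB are
# converted with a factor of 1024 MB/GB.

T1_BANDWIDTH_MBPS <- 0.193
GB_TO_MB <- 1024

#' Transmission time of a file over a fixed-bandwidth link, in seconds
#'
#' `(size_gb * 1024) / bw_mbps`. For example, 3.5 GB over a T1 line takes
#' 3584 / 0.193 = 18569.95 seconds.
#'
#' @param size_gb file size in gigabytes (1 GB = 1024 MB).
#' @param bw_mbps link bandwidth in megabytes per second; defaults to the T1
#'   figure of 0.193 MB/s.
#' @return Seconds (exact; round for display).
#' @export
transmission_seconds <- function(size_gb, bw_mbps = T1_BANDWIDTH_MBPS) {
  stopifnot(all(size_gb >= 0))
  if (any(bw_mbps <= 0)) stop("bandwidth must be positive")
  (size_gb * GB_TO_MB) / bw_mbps
}

#' Transmission time in minutes
#'
#' @inheritParams transmission_seconds
#' @return Minutes.
#' @export
transmission_minutes <- function(size_gb, bw_mbps = T1_BANDWIDTH_MBPS) {
  transmission_seconds(size_gb, bw_mbps) / 60
}

#' Build a compression report
#'
#' @param original_bytes size of the input SAM text.
#' @param encoded_bytes total size of the framed field streams before
#'   post-compression.
#' @param final_bytes size of the final container.
#' @param per_field named numeric vector of per-field stream sizes in bytes.
#' @param encode_seconds,decode_seconds wall-clock timings (NA if unknown).
#' @return Object of class `samzip_report`.
#' @export
compression_report <- function(original_bytes, encoded_bytes, final_bytes,
                               per_field = numeric(0),
                               encode_seconds = NA_real_,
                               decode_seconds = NA_real_) {
  stopifnot(original_bytes >= 0, encoded_bytes >= 0, final_bytes >= 0)
  structure(list(original_bytes = as.double(original_bytes),
                 encoded_bytes = as.double(encoded_bytes),
                 final_bytes = as.double(final_bytes),
                 ratio = if (final_bytes > 0) original_bytes / final_bytes else NA_real_,
                 per_field = per_field,
                 encode_seconds = as.double(encode_seconds),
                 decode_seconds = as.double(decode_seconds)),
            class = "samzip_report")
}

#' @export
print.samzip_report <- function(x, ...) {
  cat(sprintf("<samzip_report: %s -> %s bytes (ratio %.2f)>\n",
              format(x$original_bytes, big.mark = ","),
              format(x$final_bytes, big.mark = ","),
              x$ratio))
  invisible(x)
}

#' Total online transfer time: compress, transmit, decompress
#'
#' The sum of the compression time, the effective transmission time of the
#' final container, and the decompression time.
#'
#' @param report a `samzip_report` with non-missing timings.
#' @param bw_mbps link bandwidth in MB/s.
#' @return Seconds.
#' @export
total_online_time <- function(report, bw_mbps = T1_BANDWIDTH_MBPS) {
  stopifnot(inherits(report, "samzip_report"))
  if (is.na(report$encode_seconds) || is.na(report$decode_seconds))
    stop("report is missing encode/decode timings")
  report$encode_seconds + report$decode_seconds +
    transmission_seconds(report$final_bytes / (1024^3), bw_mbps)
}
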