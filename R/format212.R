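#' Decode a format-212 packed byte stream
#'
#' Format 212 is the packing used by MIT-BIH signal (`.dat`) files: two
#' signed 12-bit samples are stored in three bytes. For a byte triple
#' `b1, b2, b3`, the first sample is the low nibble of `b2` (as high bits)
#' over `b1`, the second is the high nibble of `b2` (as high bits) over
#' `b3`; both are two's-complement 12-bit integers in `[-2048, 2047]`.
#' An odd trailing sample occupies two bytes (`b1`, low nibble of `b2`).
#'
#' @param bytes A raw vector.
#' @param n_samples Number of samples to decode.
#' @return An integer vector of length `n_samples`.
#' @seealso [encode_format212()]
#' @export
#' @examples
#' decode_format212(as.raw(c(0x01, 0x00, 0x02)), 2)  # c(1, 2)
decode_format212 <- function(bytes, n_samples) {
  stopifnot(is.raw(bytes), n_samples >= 0)
  n_samples <- as.integer(n_samples)
  if (n_samples == 0L) return(integer(0))
  needed <- ceiling(n_samples * 3 / 2)
  if (length(bytes) < needed) {
    ecg_abort(
      sprintf(
        "truncated format-212 stream: need %d bytes for %d samples, have %d (short by %d at byte offset %d)",
        needed, n_samples, length(bytes), needed - length(bytes), length(bytes)
      ),
      "ecgkit_decode_error"
    )
  }
  b <- as.integer(bytes)
  n_pairs <- n_samples %/% 2L
  out <- integer(n_samples)
  if (n_pairs > 0L) {
    base <- (seq_len(n_pairs) - 1L) * 3L
    b1 <- b[base + 1L]; b2 <- b[base + 2L]; b3 <- b[base + 3L]
    s1 <- bitwOr(bitwShiftL(bitwAnd(b2, 0x0FL), 8L), b1)
    s2 <- bitwOr(bitwShiftL(bitwAnd(b2, 0xF0L), 4L), b3)
    out[seq(1L, 2L * n_pairs, by = 2L)] <- s1
    out[seq(2L, 2L * n_pairs, by = 2L)] <- s2
  }
  if (n_samples %% 2L == 1L) {
    off <- n_pairs * 3L
    out[n_samples] <- bitwOr(bitwShiftL(bitwAnd(b[off + 2L], 0x0FL), 8L), b[off + 1L])
  }
  # two's complement sign extension from 12 bits
  out - 4096L * (out >= 2048L)
}

#' Encode signed 12-bit integers as a format-212 byte stream
#'
#' Inverse of [decode_format212()]. Values must lie in `[-2048, 2047]`.
#'
#' @param values Integer vector of ADC values.
#' @return A raw vector of `ceiling(3 * length(values) / 2)` bytes.
#' @export
encode_format212 <- function(values) {
  values <- as.integer(values)
  if (any(values < -2048L | values > 2047L)) {
    ecg_abort("format-212 values must lie in [-2048, 2047]", "ecgkit_range_error")
  }
  n <- length(values)
  if (n == 0L) return(raw(0))
  u <- values + 4096L * (values < 0L)  # unsigned 12-bit
  n_pairs <- n %/% 2L
  bytes <- integer(ceiling(n * 3 / 2))
  if (n_pairs > 0L) {
    s1 <- u[seq(1L, 2L * n_pairs, by = 2L)]
    s2 <- u[seq(2L, 2L * n_pairs, by = 2L)]
    base <- (seq_len(n_pairs) - 1L) * 3L
    bytes[base + 1L] <- bitwAnd(s1, 0xFFL)
    bytes[base + 2L] <- bitwOr(bitwShiftR(s1, 8L), bitwShiftL(bitwShiftR(s2, 8L), 4L))
    bytes[base + 3L] <- bitwAnd(s2, 0xFFL)
  }
  if (n %% 2L == 1L) {
    off <- n_pairs * 3L
    bytes[off + 1L] <- bitwAnd(u[n], 0xFFL)
    bytes[off + 2L] <- bitwShiftR(u[n], 8L)
  }
  as.raw(bytes)
}
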