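#' Mutable bit stream with MSB-first byte packing
#'
#' A `bitstream` is an append-only sequence of bits with a read cursor,
#' the substrate shared by all coders in the package. It is implemented as an
#' environment so that reads advance the cursor in place, the way file
#' connections behave.
#'
#' @param bits optional initial bits (anything [as_bits()] accepts).
#' @return an object of class `bitstream`.
#' @examples
#' bs <- bitstream("1101100101")
#' read_bits(bs, 4)
#' scan_for_pattern(bs, "01")
#' @seealso [append_bits()], [read_bits()], [scan_for_pattern()]
#' @export
bitstream <- function(bits = NULL) {
  bs <- new.env(parent = emptyenv())
  bs$buf <- integer(64L)
  bs$len <- 0L
  bs$cursor <- 0L  # bits already consumed
  class(bs) <- "bitstream"
  if (!is.null(bits)) append_bits(bs, bits)
  bs
}

#' Append bits to a stream
#'
#' @param bs a [bitstream()].
#' @param bits bits to append (anything [as_bits()] accepts); appending an
#'   empty sequence leaves the stream unchanged.
#' @return `bs`, invisibly.
#' @export
append_bits <- function(bs, bits) {
  stopifnot(inherits(bs, "bitstream"))
  bits <- as_bits(bits)
  n <- length(bits)
  if (n == 0L) return(invisible(bs))
  need <- bs$len + n
  if (need > length(bs$buf)) {
    newcap <- max(2L * length(bs$buf), need)
    buf <- integer(newcap)
    buf[seq_len(bs$len)] <- bs$buf[seq_len(bs$len)]
    bs$buf <- buf
  }
  bs$buf[bs$len + seq_len(n)] <- bits
  bs$len <- bs$len + n
  invisible(bs)
}

#' Read bits from a stream, advancing the cursor
#'
#' Reading past the end raises an error of class `blcodec_overrun`, which is
#' distinguishable from having cleanly consumed the stream (use
#' [bits_remaining()] to test for end-of-stream at a symbol boundary).
#'
#' @param bs a [bitstream()].
#' @param n number of bits to read (`n = 0` returns an empty vector).
#' @return integer vector of `n` bits.
#' @export
read_bits <- function(bs, n) {
  stopifnot(inherits(bs, "bitstream"))
  n <- check_count(n, "n")
  if (bs$cursor + n > bs$len)
    stop(errorCondition(
      sprintf("attempt to read %d bits with only %d remaining",
              n, bs$len - bs$cursor),
      class = c("blcodec_overrun", "blcodec_error")))
  if (n == 0L) return(integer(0))
  out <- bs$buf[bs$cursor + seq_len(n)]
  bs$cursor <- bs$cursor + as.integer(n)
  out
}

#' Locate a bit pattern ahead of the cursor
#'
#' Returns the number of bits from the cursor through the *end* of the first
#' occurrence of `pattern`, without moving the cursor. This is the primitive
#' the BL decoder uses to delimit a prefix at its terminating "01".
#'
#' @param bs a [bitstream()].
#' @param pattern non-empty bit pattern (anything [as_bits()] accepts).
#' @return integer count of bits up to and including the first occurrence.
#' @export
scan_for_pattern <- function(bs, pattern) {
  stopifnot(inherits(bs, "bitstream"))
  pattern <- as_bits(pattern)
  m <- length(pattern)
  if (m == 0L) stop("pattern must be non-empty", call. = FALSE)
  avail <- bs$len - bs$cursor
  if (avail >= m) {
    window <- bs$buf[bs$cursor + seq_len(avail)]
    hit <- TRUE
    for (j in seq_len(m)) {
      idx <- seq_len(avail - m + 1L) + (j - 1L)
      hit <- hit & (window[idx] == pattern[j])
    }
    w <- which(hit)
    if (length(w)) return(w[1L] + m - 1L)
  }
  stop(errorCondition(
    "pattern not found before end of stream (truncated or corrupt code)",
    class = c("blcodec_truncated", "blcodec_error")))
}

#' @rdname read_bits
#' @export
bits_remaining <- function(bs) {
  stopifnot(inherits(bs, "bitstream"))
  bs$len - bs$cursor
}

#' @export
length.bitstream <- function(x) x$len

#' @export
print.bitstream <- function(x, ...) {
  shown <- min(x$len, 64L)
  cat(sprintf("<bitstream: %d bits, cursor at %d>\n", x$len, x$cursor))
  if (shown > 0)
    cat(bits_to_string(x$buf[seq_len(shown)]),
        if (x$len > shown) "..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
as.integer.bitstream <- function(x, ...) x$buf[seq_len(x$len)]

# Remaining (unread) bits as a plain integer vector; used by the vectorised
# sequence decoders, which then advance the cursor themselves.
bs_tail <- function(bs) bs$buf[bs$cursor + seq_len(bs$len - bs$cursor)]

bs_advance <- function(bs, n) {
  bs$cursor <- bs$cursor + as.integer(n)
  invisible(bs)
}
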