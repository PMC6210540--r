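#' Convert a bit representation to an integer 0/1 vector
#'
#' The package's internal currency for codewords is a plain integer vector of
#' 0s and 1s, ordered left to right exactly as code tables print bit strings.
#' `as_bits()` accepts a character scalar such as `"1101"`, a logical vector,
#' or a numeric/integer vector of 0s and 1s.
#'
#' @param x bits as a single string, or a logical/numeric/integer vector.
#' @return integer vector of 0L/1L.
#' @examples
#' as_bits("010")
#' bits_to_string(as_bits("010"))
#' @export
as_bits <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    if (nchar(x) == 0L) return(integer(0))
    x <- strsplit(x, "", fixed = TRUE)[[1L]]
    if (!all(x %in% c("0", "1")))
      stop("bit string may contain only '0' and '1'", call. = FALSE)
    return(as.integer(x == "1"))
  }
  if (is.logical(x)) return(as.integer(x))
  x <- as.integer(x)
  if (length(x) && !all(x == 0L | x == 1L))
    stop("bits must be 0 or 1", call. = FALSE)
  x
}

#' @rdname as_bits
#' @param bits integer vector of 0L/1L.
#' @export
bits_to_string <- function(bits) paste(bits, collapse = "")

#' Pack bits into bytes (MSB-first) and unpack them again
#'
#' The first bit written becomes the highest-order bit of the first byte; a
#' final partial byte is zero-padded on the right. Decoders never rely on the
#' padding: the symbol count recorded alongside a payload terminates decoding.
#'
#' @param bits integer vector of 0L/1L.
#' @return `pack_bits()`: a raw vector of `ceiling(length(bits)/8)` bytes.
#' @examples
#' r <- pack_bits(as_bits("101000001"))
#' unpack_bits(r, 9)
#' @export
pack_bits <- function(bits) {
  bits <- as_bits(bits)
  n <- length(bits)
  if (n == 0L) return(raw(0))
  pad <- (-n) %% 8L
  m <- matrix(c(bits, integer(pad)), nrow = 8L)
  # packBits() consumes bits LSB-first within each byte; flip row order so the
  # first appended bit lands in the MSB.
  packBits(as.logical(m[8:1, , drop = FALSE]), type = "raw")
}

#' @rdname pack_bits
#' @param bytes raw vector produced by [pack_bits()].
#' @param nbits number of valid bits to recover (padding is discarded).
#' @return `unpack_bits()`: the original integer 0/1 vector of length `nbits`.
#' @export
unpack_bits <- function(bytes, nbits) {
  stopifnot(is.raw(bytes), nbits >= 0)
  if (nbits == 0L) return(integer(0))
  if (nbits > 8 * length(bytes))
    stop("nbits exceeds the number of packed bits", call. = FALSE)
  b <- as.integer(rawToBits(bytes))
  m <- matrix(b, nrow = 8L)
  as.vector(m[8:1, , drop = FALSE])[seq_len(nbits)]
}

# Exact floor(log2(z)) for z >= 1 representable in a double; guards against
# floating-point log2() landing on the wrong side at exact powers of two.
ilog2 <- function(z) {
  k <- floor(log2(z))
  k <- k - (2^k > z)
  k + (2^(k + 1) <= z)
}

# Interpret many variable-width big-endian bit chunks at once.
# starts/widths are parallel vectors; returns numeric values (exact < 2^53).
read_uint_chunks <- function(bits, starts, widths) {
  vals <- numeric(length(starts))
  if (!length(starts)) return(vals)
  for (j in seq_len(max(widths))) {
    sel <- widths >= j
    vals[sel] <- vals[sel] * 2 + bits[starts[sel] + j - 1L]
  }
  vals
}

check_count <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x != trunc(x))
    stop(sprintf("'%s' must be a single non-negative integer", name),
         call. = FALSE)
  as.numeric(x)
}
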