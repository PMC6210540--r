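#' Baseline universal coders
#'
#' Classic variable-length integer codes used as comparison points for the BL
#' code: unary, order-0 exponential Golomb (indexed so `Z = 1` maps to
#' codeword "1", the convention of the code tables this package reproduces),
#' Elias gamma, Elias delta, and Fibonacci (Zeckendorf) coding. Under the
#' shifted indexing the exponential Golomb codeword of `Z` coincides bit for
#' bit with the Elias gamma codeword of `Z`; both are kept as separate entry
#' points because their constructions, and their usual generalisations,
#' differ.
#'
#' @param N,Z positive integer value(s) to encode (vectorised).
#' @param bs a [bitstream()] positioned at a codeword boundary (for decoders).
#' @name reference_codes
NULL

#' @describeIn reference_codes unary code: `N - 1` zeros then a single one.
#' @return encoders return character vectors of bit strings; decoders return a
#'   list with `value` and `bits_consumed`.
#' @examples
#' unary_encode(1:4)        # "1" "01" "001" "0001"
#' exp_golomb_encode(10)    # "0001010"
#' elias_gamma_encode(1)    # "1"
#' fibonacci_encode(1000000)  # 30 bits
#' @export
unary_encode <- function(N) {
  N <- check_positive(N, "N", limit = 2^31)
  paste0(strrep("0", N - 1), "1")
}

#' @describeIn reference_codes order-0 exponential Golomb code of `Z - 1`:
#'   `floor(log2 Z)` zeros followed by the `floor(log2 Z) + 1`-bit binary
#'   expansion of `Z`; total length `2*floor(log2 Z) + 1`.
#' @export
exp_golomb_encode <- function(Z) {
  Z <- check_positive(Z, "Z")
  k <- ilog2(Z)
  paste0(strrep("0", k), vapply(Z, to_binary_string, ""))
}

#' @describeIn reference_codes inverse of [exp_golomb_encode()], consuming one
#'   codeword from the stream.
#' @export
exp_golomb_decode <- function(bs) {
  decode_one_gamma_like(bs)
}

#' @describeIn reference_codes Elias gamma code: identical construction,
#'   `floor(log2 Z)` zeros then `binary(Z)`.
#' @export
elias_gamma_encode <- function(Z) exp_golomb_encode(Z)

#' @describeIn reference_codes inverse of [elias_gamma_encode()].
#' @export
elias_gamma_decode <- function(bs) decode_one_gamma_like(bs)

#' @describeIn reference_codes Elias delta code: the gamma code of
#'   `floor(log2 Z) + 1` followed by the `floor(log2 Z)` low-order bits of `Z`.
#' @export
elias_delta_encode <- function(Z) {
  Z <- check_positive(Z, "Z")
  k <- ilog2(Z)
  lowbits <- mapply(function(z, kk) {
    if (kk == 0) "" else to_binary_string(z - 2^kk, width = kk)
  }, Z, k)
  paste0(exp_golomb_encode(k + 1), lowbits)
}

#' @describeIn reference_codes inverse of [elias_delta_encode()].
#' @export
elias_delta_decode <- function(bs) {
  g <- decode_one_gamma_like(bs)
  k <- g$value - 1
  if (bits_remaining(bs) < k)
    stop(errorCondition("truncated Elias delta codeword",
                        class = c("blcodec_truncated", "blcodec_error")))
  low <- if (k > 0) read_uint_chunks(read_bits(bs, k), 1L, k) else 0
  list(value = 2^k + low, bits_consumed = g$bits_consumed + k)
}

#' @describeIn reference_codes Fibonacci code: Zeckendorf representation over
#'   `F(2) = 1, F(3) = 2, ...` (least significant digit first), terminated by
#'   an appended "1", so every codeword ends in "11" and contains no other
#'   adjacent ones.
#' @export
fibonacci_encode <- function(Z) {
  Z <- check_positive(Z, "Z")
  if (!length(Z)) return(character(0))
  bits <- fib_encode_bits(Z)
  len <- fib_lengths(Z)
  ends <- cumsum(len)
  s <- bits_to_string(bits)
  substring(s, ends - len + 1, ends)
}

#' @describeIn reference_codes inverse of [fibonacci_encode()].
#' @export
fibonacci_decode <- function(bs) {
  stopifnot(inherits(bs, "bitstream"))
  end <- scan_for_pattern(bs, c(1L, 1L))  # ends at the second 1 of "11"
  word <- read_bits(bs, end)
  f <- fib_table_upto(end)
  list(value = sum(f[seq_len(end - 1L)] * word[seq_len(end - 1L)]),
       bits_consumed = end)
}

# --- shared internals -------------------------------------------------------

to_binary_string <- function(z, width = ilog2(z) + 1) {
  if (width == 0) return("")
  bits_to_string((z %/% 2^((width - 1):0)) %% 2)
}

decode_one_gamma_like <- function(bs) {
  stopifnot(inherits(bs, "bitstream"))
  lead <- scan_for_pattern(bs, 1L)  # bits through the first 1
  k <- lead - 1L
  if (bits_remaining(bs) < 2L * k + 1L)
    stop(errorCondition("truncated codeword",
                        class = c("blcodec_truncated", "blcodec_error")))
  word <- read_bits(bs, 2L * k + 1L)
  list(value = read_uint_chunks(word, k + 1L, k + 1L),
       bits_consumed = 2L * k + 1L)
}

# Fibonacci numbers F(2)=1, F(3)=2, ... up to at least `n` terms or value zmax.
fib_table_upto <- function(nterms) {
  f <- numeric(max(nterms, 2L))
  f[1] <- 1; f[2] <- 2
  i <- 2L
  while (i < nterms) {
    i <- i + 1L
    f[i] <- f[i - 1L] + f[i - 2L]
  }
  f[seq_len(max(nterms, 2L))]
}

fib_table_for <- function(zmax) {
  f <- c(1, 2)
  while (f[length(f)] < zmax)
    f <- c(f, f[length(f)] + f[length(f) - 1])
  f
}

fib_lengths <- function(Z) {
  f <- fib_table_for(max(Z))
  findInterval(Z, f) + 1
}

# Vectorised Fibonacci encoder: greedy (Zeckendorf) top-down over the table.
fib_encode_bits <- function(Z) {
  f <- fib_table_for(max(Z))
  top <- findInterval(Z, f)
  L <- top + 1
  off <- cumsum(c(0, L))[seq_along(Z)]
  bits <- integer(sum(L))
  rem <- Z
  for (j in rev(seq_along(f))) {
    take <- top >= j & rem >= f[j]
    bits[off[take] + j] <- 1L
    rem[take] <- rem[take] - f[j]
  }
  bits[off + L] <- 1L  # terminator
  bits
}

# --- generic per-coder sequence interface ----------------------------------

CODER_IDS <- c("bl" = 1L, "exp-golomb" = 2L, "elias-gamma" = 3L,
               "elias-delta" = 4L, "fibonacci" = 5L)

check_coder <- function(coder) {
  if (!(length(coder) == 1L && coder %in% names(CODER_IDS)))
    stop(sprintf("unknown coder '%s'; available: %s",
                 paste(coder, collapse = ","),
                 paste(names(CODER_IDS), collapse = ", ")), call. = FALSE)
  coder
}

# Concatenated codeword bits for a value vector under any supported coder.
encode_values_bits <- function(values, coder, S = 1) {
  coder <- check_coder(coder)
  values <- check_positive(values, "values")
  switch(coder,
    "bl" = bl_encode_bits(values, S),
    "exp-golomb" = ,
    "elias-gamma" = gamma_encode_bits(values),
    "elias-delta" = delta_encode_bits(values),
    "fibonacci" = fib_encode_bits(values))
}

decode_values_bits <- function(bits, count, coder, S = 1) {
  coder <- check_coder(coder)
  switch(coder,
    "bl" = bl_decode_bits(bits, count, S),
    "exp-golomb" = ,
    "elias-gamma" = gamma_decode_bits(bits, count),
    "elias-delta" = delta_decode_bits(bits, count),
    "fibonacci" = fib_decode_bits(bits, count))
}

gamma_encode_bits <- function(Z) {
  k <- ilog2(Z)
  L <- 2 * k + 1
  n <- length(Z)
  off <- cumsum(c(0, L))[seq_len(n)]
  bits <- integer(sum(L))
  w <- k + 1
  for (j in seq_len(max(w))) {
    sel <- w >= j
    b1 <- (Z[sel] %/% 2^(w[sel] - j)) %% 2 == 1
    bits[(off[sel] + k[sel] + j)[b1]] <- 1L
  }
  bits
}

gamma_decode_bits <- function(bits, count) {
  n <- length(bits)
  pos1 <- which(bits == 1L)
  i1 <- 1L
  start <- integer(count); width <- numeric(count)
  p <- 1L
  for (s in seq_len(count)) {
    while (i1 <= length(pos1) && pos1[i1] < p) i1 <- i1 + 1L
    if (i1 > length(pos1))
      stop(errorCondition(
        sprintf("truncated stream at symbol %d", s),
        class = c("blcodec_truncated", "blcodec_error")))
    k <- pos1[i1] - p
    if (p + 2L * k > n)
      stop(errorCondition(
        sprintf("truncated stream at symbol %d", s),
        class = c("blcodec_truncated", "blcodec_error")))
    start[s] <- p + k; width[s] <- k + 1
    p <- as.integer(p + 2L * k + 1L)
  }
  list(values = read_uint_chunks(bits, start, width), bits_consumed = p - 1L)
}

delta_encode_bits <- function(Z) {
  k <- ilog2(Z)
  kk <- ilog2(k + 1)
  L <- 2 * kk + 1 + k
  n <- length(Z)
  off <- cumsum(c(0, L))[seq_len(n)]
  bits <- integer(sum(L))
  w1 <- kk + 1                        # gamma part: binary of k+1
  for (j in seq_len(max(w1))) {
    sel <- w1 >= j
    b1 <- ((k[sel] + 1) %/% 2^(w1[sel] - j)) %% 2 == 1
    bits[(off[sel] + kk[sel] + j)[b1]] <- 1L
  }
  low <- Z - 2^k                      # k low-order bits of Z
  for (j in seq_len(max(k, 1))) {
    sel <- k >= j
    if (!any(sel)) break
    b1 <- (low[sel] %/% 2^(k[sel] - j)) %% 2 == 1
    bits[(off[sel] + 2 * kk[sel] + 1 + j)[b1]] <- 1L
  }
  bits
}

delta_decode_bits <- function(bits, count) {
  n <- length(bits)
  pos1 <- which(bits == 1L)
  i1 <- 1L
  start <- integer(count); width <- numeric(count)
  p <- 1L
  for (s in seq_len(count)) {
    while (i1 <= length(pos1) && pos1[i1] < p) i1 <- i1 + 1L
    if (i1 > length(pos1))
      stop(errorCondition(
        sprintf("truncated stream at symbol %d", s),
        class = c("blcodec_truncated", "blcodec_error")))
    kk <- pos1[i1] - p
    if (p + 2L * kk > n)
      stop(errorCondition(
        sprintf("truncated stream at symbol %d", s),
        class = c("blcodec_truncated", "blcodec_error")))
    Lval <- read_uint_chunks(bits, p + kk, kk + 1)
    k <- Lval - 1
    if (p + 2L * kk + k > n)
      stop(errorCondition(
        sprintf("truncated stream at symbol %d", s),
        class = c("blcodec_truncated", "blcodec_error")))
    start[s] <- p + 2L * kk + 1L; width[s] <- k
    p <- as.integer(p + 2L * kk + 1L + k)
  }
  low <- numeric(count)
  pos <- width > 0
  low[pos] <- read_uint_chunks(bits, start[pos], width[pos])
  k <- numeric(count)
  k[] <- width
  list(values = 2^k + low, bits_consumed = p - 1L)
}

fib_decode_bits <- function(bits, count) {
  n <- length(bits)
  pos11 <- if (n >= 2L) which(bits[-n] == 1L & bits[-1L] == 1L) else integer(0)
  i11 <- 1L
  values <- numeric(count)
  fmax <- fib_table_for(2^52)
  p <- 1L
  for (s in seq_len(count)) {
    while (i11 <= length(pos11) && pos11[i11] < p) i11 <- i11 + 1L
    if (i11 > length(pos11))
      stop(errorCondition(
        sprintf("truncated stream at symbol %d", s),
        class = c("blcodec_truncated", "blcodec_error")))
    q <- pos11[i11]                 # data bits p..q, terminator at q+1
    top <- q - p + 1L
    values[s] <- sum(fmax[seq_len(top)] * bits[p:q])
    p <- as.integer(q + 2L)
  }
  list(values = values, bits_consumed = p - 1L)
}

#' Per-integer codeword lengths for a set of coders
#'
#' One row per integer `1..z_max`, one column per coder, each entry the bit
#' length of that coder's codeword. Reproduces the bit-length comparison
#' curves in which the BL code undercuts the exponential Golomb code for all
#' but the smallest integers.
#'
#' @param z_max largest integer to tabulate.
#' @param coders character vector drawn from `"bl"`, `"unary"`,
#'   `"exp-golomb"`, `"elias-gamma"`, `"elias-delta"`, `"fibonacci"`.
#' @param S BL suffix parameter.
#' @return data frame with column `Z` and one length column per coder.
#' @examples
#' tab <- codeword_length_table(100)
#' tab[tab$Z == 100, ]  # BL 10 bits, exponential Golomb 13 bits
#' @export
codeword_length_table <- function(z_max,
                                  coders = c("bl", "exp-golomb", "elias-gamma",
                                             "elias-delta", "fibonacci"),
                                  S = 1) {
  z_max <- check_positive(z_max, "z_max")
  stopifnot(length(z_max) == 1L)
  Z <- seq_len(z_max)
  known <- c("bl", "unary", names(CODER_IDS))
  bad <- setdiff(coders, known)
  if (length(bad))
    stop(sprintf("unknown coder '%s'", bad[1L]), call. = FALSE)
  out <- data.frame(Z = Z)
  for (cd in coders) {
    out[[cd]] <- switch(cd,
      "bl" = bl_codeword_length(Z, S),
      "unary" = Z,
      "exp-golomb" = ,
      "elias-gamma" = 2 * ilog2(Z) + 1,
      "elias-delta" = 1 + ilog2(Z) + 2 * ilog2(ilog2(Z) + 1),
      "fibonacci" = fib_lengths(Z))
  }
  out
}
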