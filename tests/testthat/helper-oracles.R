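# Independent oracles used to freeze expected values; deliberately naive and
# separate from the implementation paths they check.

# Naive substring search over bit vectors: position just past the end of the
# first occurrence of pattern, or NA.
naive_scan <- function(bits, pattern) {
  n <- length(bits); m <- length(pattern)
  if (n >= m) for (i in seq_len(n - m + 1L)) {
    if (all(bits[i:(i + m - 1L)] == pattern)) return(i + m - 1L)
  }
  NA_integer_
}

# Group index by brute-force enumeration of the triangular bounds.
oracle_group_index <- function(M) {
  K <- 1
  while (M > K * (K + 1) / 2) K <- K + 1
  K
}

# Strict-floor form of the published group-index formula: the largest integer
# strictly smaller than (1 + sqrt(1 + 8M)) / 2.
strict_floor_group_index <- function(M) {
  x <- (1 + sqrt(1 + 8 * M)) / 2
  k <- floor(x)
  ifelse(k == x, k - 1, k)
}

# Smallest code-num M with Z <= 2^S (2^M - 1), by linear search.
oracle_code_num <- function(Z, S = 1) {
  M <- 1
  while (Z > 2^S * (2^M - 1)) M <- M + 1
  M
}

random_sample_frame <- function(rows, cols, bit_depth, stage = "beamformed",
                                sd = 2^(bit_depth - 4)) {
  lim <- 2^(bit_depth - 1)
  v <- pmin(pmax(round(rnorm(rows * cols, 0, sd)), -lim), lim - 1)
  sample_frame(matrix(as.integer(v), rows, cols), stage = stage,
               bit_depth = bit_depth)
}
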