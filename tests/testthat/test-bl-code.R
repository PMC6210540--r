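test_that("group index and within-group position match the worked examples", {
  expect_equal(group_index(5), 3)     # cluster 1001 has K = 3
  expect_equal(group_index(1), 1)
  expect_equal(group_index(19), oracle_group_index(19))  # = 6
  expect_equal(position_in_group(10), 4)
  expect_equal(position_in_group(1), 1)
  expect_equal(position_in_group(19), 4)
  expect_error(group_index(0), "positive")
  expect_error(position_in_group(-3), "positive")
})

test_that("cluster enumeration reproduces the printed table for M = 1..10", {
  expect_equal(binary_cluster(1:10),
               c("10", "100", "101", "1000", "1001", "1011",
                 "10000", "10001", "10011", "10111"))
  expect_equal(bl_prefix(1:10),
               c("01", "001", "101", "0001", "1001", "1101",
                 "00001", "10001", "11001", "11101"))
  expect_equal(group_index(1:10), c(1, 2, 2, 3, 3, 3, 4, 4, 4, 4))
  expect_equal(binary_cluster(19), "1000111")
})

test_that("clusters start with 10, contain exactly one 10, and prefixes end 01", {
  M <- 1:10000
  cl <- binary_cluster(M)
  pf <- bl_prefix(M)
  expect_true(all(substr(cl, 1, 2) == "10"))
  count10 <- lengths(gregexpr("10", cl, fixed = TRUE))
  expect_true(all(count10 == 1L))
  count01 <- lengths(gregexpr("01", pf, fixed = TRUE))
  expect_true(all(count01 == 1L))
  expect_true(all(substr(pf, nchar(pf) - 1, nchar(pf)) == "01"))
  # leading ones in the prefix = X - 1
  lead_ones <- nchar(sub("0.*$", "", pf))
  expect_equal(lead_ones, position_in_group(M) - 1)
})

test_that("integer-search group index equals the strict-floor formula up to 1e6", {
  M <- seq_len(1e6)
  expect_equal(group_index(M), strict_floor_group_index(M))
})

test_that("code-num assignment matches the worked examples and the oracle", {
  expect_equal(code_num_for_value(100), 6)
  expect_equal(code_num_for_value(16), 4)
  expect_equal(code_num_for_value(1e6), oracle_code_num(1e6))  # = 19
  expect_equal(code_num_for_value(1e6), 19)
  # no floating-point ceil ties at exact powers of two
  for (Z in c(1, 2, 3, 6, 7, 14, 15, 30, 62, 126, 127, 1024)) {
    expect_equal(code_num_for_value(Z, 1), oracle_code_num(Z, 1))
    expect_equal(code_num_for_value(Z, 2), oracle_code_num(Z, 2))
  }
  expect_error(code_num_for_value(0), "positive")
})

test_that("encoding reproduces the printed codewords, including corrected Z=15", {
  expect_equal(bl_encode(1:16),
               c("010", "011", "00100", "00101", "00110", "00111",
                 "101000", "101001", "101010", "101011", "101100", "101101",
                 "101110", "101111", "00010000", "00010001"))
  expect_equal(bl_encode(1e6), "11100011110100001001000001")
  expect_equal(nchar(bl_encode(1e6)), 26)
  expect_error(bl_encode(c(3, 0)), "positive")
})

test_that("codeword length formula K + M + S matches materialised codewords", {
  expect_equal(bl_codeword_length(100), 10)
  expect_equal(bl_codeword_length(1000), 14)
  expect_equal(bl_codeword_length(1e6), 26)
  Z <- seq_len(1e5)
  for (S in c(1, 3)) {
    M <- code_num_for_value(Z, S)
    expect_equal(bl_codeword_length(Z, S), group_index(M) + M + S)
  }
  expect_equal(bl_codeword_length(seq_len(2000)), nchar(bl_encode(seq_len(2000))))
})

test_that("prefix decoding recovers M from K and the leading-ones count", {
  d <- bl_decode_prefix(bitstream("1101100101"))
  expect_equal(d$M, 6)
  expect_equal(d$bits_consumed, 4L)
  d <- bl_decode_prefix(bitstream("01"))
  expect_equal(d$M, 1)
  expect_equal(d$bits_consumed, 2L)
  d <- bl_decode_prefix(bitstream("111010000000001"))
  expect_equal(d$M, 10)
  expect_equal(d$bits_consumed, 5L)
})

test_that("value decoding reproduces the published stream examples", {
  d <- bl_decode_value(bitstream("1101100101"))
  expect_equal(d$value, 100)
  expect_equal(d$bits_consumed, 10)
  d <- bl_decode_value(bitstream("111010000000001"))
  expect_equal(d$value, 1024)
  expect_equal(d$bits_consumed, 15)
  d <- bl_decode_value(bitstream("010"))
  expect_equal(d$value, 1)
  expect_equal(d$bits_consumed, 3)
  expect_error(bl_decode_value(bitstream("110110")),
               class = "blcodec_truncated")
})

test_that("sequences concatenate with no separators and invert exactly", {
  bs <- bl_encode_sequence(c(100, 1024))
  expect_equal(bits_to_string(as.integer(bs)),
               paste0("1101100101", "111010000000001"))
  expect_equal(bl_decode_sequence(bitstream("1101100101111010000000001"), 2),
               c(100, 1024))
  expect_equal(length(bl_encode_sequence(numeric(0))), 0L)
  expect_equal(bl_decode_sequence(bitstream("1101100101"), 0), numeric(0))
  bs <- bl_encode_sequence(1:3)
  expect_equal(bits_to_string(as.integer(bs)), "01001100100")
  err <- tryCatch(bl_decode_sequence(bitstream("0100110010"), 3),
                  condition = identity)
  expect_s3_class(err, "blcodec_truncated")
  expect_match(conditionMessage(err), "symbol 3")
})

test_that("encode/decode is the identity for Z = 1..1e5 at S in 1..3", {
  Z <- seq_len(1e5)
  for (S in 1:3) {
    bs <- bl_encode_sequence(Z, S)
    expect_identical(bl_decode_sequence(bs, length(Z), S), as.numeric(Z))
  }
})

test_that("random concatenations are uniquely decodable", {
  set.seed(403)
  for (i in 1:100) {
    v <- sample.int(1e6, 1000, replace = TRUE)
    bs <- bl_encode_sequence(v)
    expect_identical(bl_decode_sequence(bs, 1000), as.numeric(v))
  }
})

test_that("for S=1 each code-num owns a contiguous range enumerated in order", {
  for (M in 1:12) {
    lo <- 2 * (2^(M - 1) - 1) + 1
    hi <- 2 * (2^M - 1)
    Z <- lo:hi
    expect_true(all(code_num_for_value(Z) == M))
    if (lo > 1) expect_equal(code_num_for_value(lo - 1), M - 1)
    # suffix enumerates the range in order: codewords share the prefix and
    # their suffix values are 0, 1, 2, ...
    cw <- bl_encode(Z)
    pfx <- bl_prefix(M)
    expect_true(all(startsWith(cw, pfx)))
    sfx <- substring(cw, nchar(pfx) + 1)
    expect_true(all(nchar(sfx) == M))     # M + S - 1 with S = 1
    expect_equal(strtoi(sfx, base = 2), 0:(hi - lo))
  }
})

test_that("large values beyond exact double range are rejected", {
  expect_error(bl_encode(2^53), "2\\^53")
  expect_equal(bl_decode_value(bitstream(bl_encode(2^52)))$value, 2^52)
})
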