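test_that("generation is a pure function of config + seed", {
  cfg <- phantom_config(rows = 256, cols = 16, seed = 21)
  f1 <- generate_rf_frame(cfg)
  f2 <- generate_rf_frame(cfg)
  expect_identical(f1$samples, f2$samples)
  f3 <- generate_rf_frame(phantom_config(rows = 256, cols = 16, seed = 22))
  expect_false(identical(f1$samples, f3$samples))
  # generation does not disturb the caller's RNG stream
  set.seed(99); a <- rnorm(3)
  set.seed(99); invisible(generate_rf_frame(cfg)); b <- rnorm(3)
  expect_identical(a, b)
})

test_that("zero speckle amplitude with no targets yields an all-zero frame", {
  cfg <- phantom_config(rows = 128, cols = 4, speckle_amplitude = 0, seed = 1)
  fr <- generate_rf_frame(cfg)
  expect_true(all(fr$samples == 0L))
})

test_that("targets and cysts must lie within frame bounds", {
  expect_error(phantom_config(rows = 64, cols = 8,
                              point_targets = data.frame(row = 100, col = 2,
                                                         amplitude = 10)),
               "bounds")
  expect_error(phantom_config(rows = 64, cols = 8,
                              cyst_regions = data.frame(row = 10, col = 20,
                                                        radius = 5,
                                                        echogenicity = 0.5)),
               "bounds")
  expect_error(phantom_config(rows = 64, cols = 8,
                              cyst_regions = data.frame(row = 10, col = 2,
                                                        radius = 5,
                                                        echogenicity = 1.5)),
               "echogenicity")
})

test_that("speckle envelope is Rayleigh: KS distance below 0.02 at n = 1e5", {
  cfg <- phantom_config(rows = 4096, cols = 128, speckle_amplitude = 200,
                        bit_depth = 16, seed = 11)
  fr <- generate_rf_frame(cfg)
  iq <- quadrature_demodulate(fr, decimation = 4)
  interior <- 33:(nrow(iq$I$samples) - 32)        # drop filter-edge taper
  env <- sqrt(as.numeric(iq$I$samples[interior, ])^2 +
              as.numeric(iq$Q$samples[interior, ])^2)
  env <- env[seq_len(1e5)]
  sigma <- sqrt(mean(env^2) / 2)
  D <- suppressWarnings(
    stats::ks.test(env, function(q) 1 - exp(-q^2 / (2 * sigma^2))))$statistic
  expect_lt(D, 0.02)
})

test_that("demodulating a pure tone at the carrier gives a constant envelope", {
  n <- 1024
  tone <- round(800 * cos(2 * pi * 8e6 * (0:(n - 1)) / 40e6))
  fr <- sample_frame(matrix(as.integer(tone), n, 2), stage = "beamformed",
                     bit_depth = 12)
  iq <- quadrature_demodulate(fr, decimation = 1)
  env <- sqrt(as.numeric(iq$I$samples)^2 + as.numeric(iq$Q$samples)^2)
  inner <- env[env > 0][100:900]
  expect_lt(sd(inner) / mean(inner), 0.01)
  expect_equal(mean(inner), 400, tolerance = 0.01)   # half scale, no mixer gain
})

test_that("decimation divides the row count and rejects invalid factors", {
  set.seed(411)
  fr <- random_sample_frame(256, 4, 12)
  iq <- quadrature_demodulate(fr, decimation = 4)
  expect_equal(nrow(iq$I$samples), 64)
  expect_equal(ncol(iq$Q$samples), 4)
  expect_equal(iq$I$sampling_rate, fr$sampling_rate / 4)
  expect_equal(iq$I$stage, "I")
  expect_equal(iq$Q$stage, "Q")
  expect_error(quadrature_demodulate(fr, decimation = 0), "positive integer")
  expect_error(quadrature_demodulate(fr, decimation = 2.5), "positive integer")
  expect_error(quadrature_demodulate(iq$I), "baseband")
})

test_that("clipping fraction is reported and negligible at default amplitudes", {
  cfg <- phantom_config(rows = 1024, cols = 32, seed = 31)
  fr <- generate_rf_frame(cfg)
  expect_lt(attr(fr, "clip_fraction"), 0.001)
  bf <- beamform_sum(fr, 8)
  expect_lt(attr(bf, "clip_fraction"), 0.001)
})

test_that("the benchmark suite has 4 data sets x 4 stage variants, reproducibly", {
  s1 <- make_benchmark_suite(seed = 7, rows = 256, cols = 16)
  expect_named(s1, c("point_phantom", "cyst_phantom", "nerve_like",
                     "thyroid_like"))
  for (ds in s1) {
    expect_named(ds, c("pre_beamformed", "beamformed", "I", "Q"))
    expect_equal(ds$pre_beamformed$stage, "pre-beamformed")
    expect_equal(ds$beamformed$stage, "beamformed")
    expect_equal(dim(ds$pre_beamformed$samples), c(256, 16))
    expect_equal(dim(ds$beamformed$samples), c(256, 2))
    expect_equal(dim(ds$I$samples), c(64, 2))
  }
  s2 <- make_benchmark_suite(seed = 7, rows = 256, cols = 16)
  expect_identical(lapply(s1, lapply, `[[`, "samples"),
                   lapply(s2, lapply, `[[`, "samples"))
})

test_that("compression ordering mirrors the in vitro / in vivo structure", {
  suite <- make_benchmark_suite(seed = 13)
  ratio <- function(fr) compression_ratio(frame_bits(fr),
                                          compress_frame(fr)$payload_bits)
  pre <- vapply(suite, function(d) ratio(d$pre_beamformed), 0)
  # phantoms (quiet background) compress better than tissue-like frames
  expect_gt(min(pre[c("point_phantom", "cyst_phantom")]),
            max(pre[c("nerve_like", "thyroid_like")]))
  for (d in suite) {
    # I and Q share amplitude statistics up to a pi/2 phase shift
    expect_lt(abs(ratio(d$I) - ratio(d$Q)), 1)
    # baseband amplitude is below beamformed RF amplitude
    expect_gte(ratio(d$I), ratio(d$beamformed))
  }
})
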