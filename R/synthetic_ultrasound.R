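#' Synthetic ultrasound phantom configuration
#'
#' Describes a simulated frame: fully developed speckle (white Gaussian
#' scatterers convolved with a Gaussian-windowed sinusoidal pulse, so the
#' envelope of homogeneous regions is Rayleigh distributed), optional strong
#' point reflectors, and optional anechoic/hypoechoic circular regions
#' (cysts). Defaults mirror a portable linear-array acquisition: 8 MHz centre
#' frequency sampled at 40 MHz, 12-bit ADC.
#'
#' `speckle_amplitude` is the RMS of the quantised speckle signal in ADC
#' units. The default of 20 puts typical per-channel RF well inside a 12-bit
#' range, the regime in which universal codes pay off.
#'
#' @param rows,cols frame dimensions (depth samples x channels).
#' @param center_frequency transmit centre frequency, Hz.
#' @param sampling_rate ADC sampling rate, Hz (must exceed twice the centre
#'   frequency).
#' @param speckle_amplitude RMS speckle level in ADC units.
#' @param point_targets optional matrix/data.frame with columns `row`, `col`,
#'   `amplitude`: strong reflectors added as scaled pulses.
#' @param cyst_regions optional matrix/data.frame with columns `row`, `col`,
#'   `radius`, `echogenicity` (in `[0, 1]`): scatterer strength inside the
#'   circle is multiplied by `echogenicity`.
#' @param bit_depth ADC resolution in bits.
#' @param seed integer seed; generation is a pure function of config + seed.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(rows = 2048, cols = 128,
                           center_frequency = 8e6, sampling_rate = 40e6,
                           speckle_amplitude = 20,
                           point_targets = NULL, cyst_regions = NULL,
                           bit_depth = 12, seed = 1) {
  if (rows < 8 || cols < 1) stop("invalid frame dimensions", call. = FALSE)
  if (sampling_rate <= 2 * center_frequency)
    stop("sampling rate must exceed twice the centre frequency",
         call. = FALSE)
  if (speckle_amplitude < 0) stop("negative speckle amplitude", call. = FALSE)
  pt <- normalize_spots(point_targets, c("row", "col", "amplitude"))
  cy <- normalize_spots(cyst_regions, c("row", "col", "radius",
                                        "echogenicity"))
  if (!is.null(pt) &&
      any(pt$row < 1 | pt$row > rows | pt$col < 1 | pt$col > cols))
    stop("point target outside frame bounds", call. = FALSE)
  if (!is.null(cy)) {
    if (any(cy$row < 1 | cy$row > rows | cy$col < 1 | cy$col > cols))
      stop("cyst centre outside frame bounds", call. = FALSE)
    if (any(cy$echogenicity < 0 | cy$echogenicity > 1))
      stop("cyst echogenicity must lie in [0, 1]", call. = FALSE)
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 center_frequency = center_frequency,
                 sampling_rate = sampling_rate,
                 speckle_amplitude = speckle_amplitude,
                 point_targets = pt, cyst_regions = cy,
                 bit_depth = as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

normalize_spots <- function(x, cols) {
  if (is.null(x)) return(NULL)
  x <- as.data.frame(x)
  if (!all(cols %in% names(x)))
    names(x) <- cols[seq_along(names(x))]
  stopifnot(all(cols %in% names(x)))
  x[cols]
}

# Run expr under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Gaussian-windowed sinusoidal pulse, unit peak envelope; fractional -6 dB
# bandwidth 0.6 (typical linear array).
ultrasound_pulse <- function(center_frequency, sampling_rate,
                             fractional_bw = 0.6) {
  bw <- fractional_bw * center_frequency
  sigma_t <- sqrt(2 * log(2)) / (pi * bw)
  half <- max(4L, ceiling(4 * sigma_t * sampling_rate))
  t <- (-half:half) / sampling_rate
  exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * center_frequency * t)
}

# Zero-padded "same" convolution of each column with a (centred) kernel.
conv_same_cols <- function(x, h) {
  n <- nrow(x); m <- length(h)
  half <- (m - 1L) %/% 2L
  apply(x, 2L, function(col)
    convolve(col, rev(h), type = "open")[half + seq_len(n)])
}

quantize_frame <- function(x, bit_depth) {
  lo <- -2^(bit_depth - 1); hi <- 2^(bit_depth - 1) - 1
  q <- round(x)
  clip <- mean(q < lo | q > hi)
  q <- pmin(pmax(q, lo), hi)
  storage.mode(q) <- "integer"
  attr(q, "clip_fraction") <- clip
  q
}

#' Generate a synthetic pre-beamformed RF frame
#'
#' Per column, a white Gaussian scatterer sequence (scaled by cyst
#' echogenicity where applicable) is convolved with the array pulse; point
#' targets add scaled pulse echoes at their depth. The result is scaled so the
#' pure-speckle RMS equals `speckle_amplitude`, then rounded and clipped to
#' the configured bit depth. The clipped fraction is attached as attribute
#' `clip_fraction` on the returned frame. Deterministic given `config$seed`.
#'
#' @param config a [phantom_config()].
#' @return a [sample_frame()] with stage `"pre-beamformed"`.
#' @examples
#' fr <- generate_rf_frame(phantom_config(rows = 256, cols = 8, seed = 7))
#' attr(fr, "clip_fraction")
#' @export
generate_rf_frame <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  h <- ultrasound_pulse(config$center_frequency, config$sampling_rate)
  gain <- config$speckle_amplitude / sqrt(sum(h^2))
  scat <- with_seed(config$seed,
                    matrix(rnorm(config$rows * config$cols),
                           config$rows, config$cols))
  if (!is.null(config$cyst_regions)) {
    rr <- matrix(seq_len(config$rows), config$rows, config$cols)
    cc <- matrix(seq_len(config$cols), config$rows, config$cols, byrow = TRUE)
    for (i in seq_len(nrow(config$cyst_regions))) {
      cyst <- config$cyst_regions[i, ]
      inside <- (rr - cyst$row)^2 + (cc - cyst$col)^2 <= cyst$radius^2
      scat[inside] <- scat[inside] * cyst$echogenicity
    }
  }
  rf <- conv_same_cols(scat, h) * gain
  if (!is.null(config$point_targets)) {
    half <- (length(h) - 1L) %/% 2L
    for (i in seq_len(nrow(config$point_targets))) {
      tg <- config$point_targets[i, ]
      idx <- tg$row + (-half:half)
      keep <- idx >= 1 & idx <= config$rows
      rf[idx[keep], tg$col] <- rf[idx[keep], tg$col] +
        tg$amplitude * h[which(keep)]
    }
  }
  q <- quantize_frame(rf, config$bit_depth)
  out <- sample_frame(q, stage = "pre-beamformed",
                      bit_depth = config$bit_depth,
                      sampling_rate = config$sampling_rate)
  attr(out, "clip_fraction") <- attr(q, "clip_fraction")
  out
}

#' Beamformed-like frame by coherent channel summation
#'
#' Sums groups of `group` adjacent channels, emulating the amplitude growth of
#' delay-and-sum beamformation without modelling array geometry — the codec
#' responds to amplitude statistics, not image formation.
#'
#' @param frame a pre-beamformed [sample_frame()].
#' @param group number of adjacent channels summed per output scanline;
#'   must divide the channel count.
#' @return a [sample_frame()] with stage `"beamformed"`.
#' @export
beamform_sum <- function(frame, group = 8) {
  stopifnot(inherits(frame, "sample_frame"))
  nc <- ncol(frame$samples)
  if (group < 1 || nc %% group != 0)
    stop("'group' must divide the channel count", call. = FALSE)
  ng <- nc %/% group
  summed <- vapply(seq_len(ng), function(g)
    rowSums(frame$samples[, (g - 1L) * group + seq_len(group),
                          drop = FALSE]),
    numeric(nrow(frame$samples)))
  q <- quantize_frame(summed, frame$bit_depth)
  out <- sample_frame(q, stage = "beamformed", bit_depth = frame$bit_depth,
                      sampling_rate = frame$sampling_rate)
  attr(out, "clip_fraction") <- attr(q, "clip_fraction")
  out
}

#' Quadrature demodulation of an RF frame to baseband I/Q
#'
#' Mixes each column with `cos`/`-sin` at the centre frequency (no gain
#' restoration, so in-band amplitude is halved, as in typical analog front-end
#' chips), low-pass filters with a linear-phase FIR (windowed-sinc via
#' [signal::fir1()], cutoff at half the decimated Nyquist), decimates rows by
#' the requested factor, and re-quantises at the frame bit depth.
#'
#' @param frame an RF [sample_frame()] (stage `"pre-beamformed"` or
#'   `"beamformed"`).
#' @param decimation positive integer row decimation factor (up to 16 in
#'   front-end hardware).
#' @param center_frequency demodulation frequency, Hz; defaults to 8 MHz.
#' @return list with elements `I` and `Q`, each a [sample_frame()].
#' @export
quadrature_demodulate <- function(frame, decimation = 4,
                                  center_frequency = 8e6) {
  stopifnot(inherits(frame, "sample_frame"))
  if (!frame$stage %in% c("pre-beamformed", "beamformed"))
    stop("frame is already baseband", call. = FALSE)
  if (length(decimation) != 1L || decimation < 1 ||
      decimation != trunc(decimation))
    stop("'decimation' must be a positive integer", call. = FALSE)
  fs <- frame$sampling_rate
  if (fs <= 2 * center_frequency)
    stop("sampling rate must exceed twice the centre frequency",
         call. = FALSE)
  n <- nrow(frame$samples)
  t <- (seq_len(n) - 1) / fs
  osc_c <- cos(2 * pi * center_frequency * t)
  osc_s <- -sin(2 * pi * center_frequency * t)
  x <- frame$samples
  # windowed-sinc low-pass at half the decimated Nyquist
  wc <- 1 / (2 * decimation)
  taps <- signal::fir1(64, wc)
  lp <- function(m) {
    y <- apply(m, 2L, function(col) {
      v <- stats::filter(col, taps, sides = 2)
      v[is.na(v)] <- 0
      as.numeric(v)
    })
    y[seq(1L, n, by = decimation), , drop = FALSE]
  }
  keep <- function(m, stage) {
    q <- quantize_frame(m, frame$bit_depth)
    out <- sample_frame(q, stage = stage, bit_depth = frame$bit_depth,
                        sampling_rate = fs / decimation)
    attr(out, "clip_fraction") <- attr(q, "clip_fraction")
    out
  }
  list(I = keep(lp(x * osc_c), "I"), Q = keep(lp(x * osc_s), "Q"))
}

#' Synthetic benchmark suite: four data sets at four pipeline stages
#'
#' Stand-ins for the usual evaluation sets: a point-target phantom and a cyst
#' phantom (quiet gel background, sparse strong reflectors), and two
#' tissue-like frames (denser, brighter speckle with low-contrast hypoechoic
#' structure). Each data set is provided as pre-beamformed RF, beamformed-like
#' RF (8-channel coherent sums), and baseband I and Q (demodulated from the
#' beamformed frame, decimated by 4). Byte-identical for a given seed.
#'
#' @param seed integer seed.
#' @param rows,cols pre-beamformed frame dimensions.
#' @return named list of four data sets, each a named list with elements
#'   `pre_beamformed`, `beamformed`, `I`, `Q`.
#' @export
make_benchmark_suite <- function(seed = 1, rows = 1024, cols = 64) {
  configs <- list(
    point_phantom = phantom_config(
      rows, cols, speckle_amplitude = 12,
      point_targets = data.frame(
        row = round(rows * c(0.2, 0.35, 0.5, 0.65, 0.8)),
        col = round(cols * c(0.25, 0.5, 0.75, 0.4, 0.6)),
        amplitude = 600),
      seed = seed),
    cyst_phantom = phantom_config(
      rows, cols, speckle_amplitude = 12,
      cyst_regions = data.frame(
        row = round(rows * c(0.3, 0.55, 0.8)),
        col = round(cols * c(0.3, 0.65, 0.45)),
        radius = round(rows / 10),
        echogenicity = 0.1),
      seed = seed + 1L),
    nerve_like = phantom_config(
      rows, cols, speckle_amplitude = 20,
      cyst_regions = data.frame(
        row = round(rows * c(0.4, 0.6)),
        col = round(cols * c(0.4, 0.6)),
        radius = round(rows / 12),
        echogenicity = 0.65),
      seed = seed + 2L),
    thyroid_like = phantom_config(
      rows, cols, speckle_amplitude = 22,
      cyst_regions = data.frame(
        row = round(rows * c(0.25, 0.45, 0.65, 0.85)),
        col = round(cols * c(0.2, 0.5, 0.8, 0.35)),
        radius = round(rows / 16),
        echogenicity = 0.75),
      seed = seed + 3L))
  lapply(configs, function(cf) {
    pre <- generate_rf_frame(cf)
    bf <- beamform_sum(pre, group = 8)
    iq <- quadrature_demodulate(bf, decimation = 4,
                                center_frequency = cf$center_frequency)
    list(pre_beamformed = pre, beamformed = bf, I = iq$I, Q = iq$Q)
  })
}
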