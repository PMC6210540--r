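#' Signed ultrasound sample frames
#'
#' A `sample_frame` wraps a 2-D grid of signed integer samples (rows = depth
#' samples, columns = channels or scanlines) with the acquisition-stage label,
#' ADC bit depth, and sampling rate. Every sample must fit the declared bit
#' depth: \eqn{-2^{b-1} \le v \le 2^{b-1} - 1}.
#'
#' @param samples integer matrix of samples.
#' @param stage one of `"pre-beamformed"`, `"beamformed"`, `"I"`, `"Q"`.
#' @param bit_depth ADC resolution in bits (e.g. 12).
#' @param sampling_rate sampling rate in Hz (metadata only).
#' @return object of class `sample_frame`.
#' @export
sample_frame <- function(samples, stage = "pre-beamformed", bit_depth = 12,
                         sampling_rate = 40e6) {
  stopifnot(is.matrix(samples))
  stage <- match.arg(stage, names(STAGE_IDS))
  if (length(bit_depth) != 1L || bit_depth < 2 || bit_depth > 16)
    stop("'bit_depth' must be a single value in 2..16", call. = FALSE)
  storage.mode(samples) <- "integer"
  check_frame_range(samples, bit_depth)
  structure(list(samples = samples, stage = stage,
                 bit_depth = as.integer(bit_depth),
                 sampling_rate = as.numeric(sampling_rate)),
            class = "sample_frame")
}

STAGE_IDS <- c("pre-beamformed" = 1L, "beamformed" = 2L, "I" = 3L, "Q" = 4L)

check_frame_range <- function(samples, bit_depth) {
  lo <- -2^(bit_depth - 1); hi <- 2^(bit_depth - 1) - 1
  bad <- which(samples < lo | samples > hi | is.na(samples))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(samples))
    stop(sprintf(
      "sample at row %d, col %d (value %s) outside the %d-bit range [%d, %d]",
      rc[1], rc[2], format(samples[bad[1L]]), bit_depth, lo, hi),
      call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.sample_frame <- function(x, ...) {
  cat(sprintf("<sample_frame: %d x %d, stage %s, %d-bit, %.1f MHz>\n",
              nrow(x$samples), ncol(x$samples), x$stage, x$bit_depth,
              x$sampling_rate / 1e6))
  invisible(x)
}

#' @export
dim.sample_frame <- function(x) dim(x$samples)

#' Zigzag mapping between signed integers and positive code integers
#'
#' Universal codes are defined on positive integers, while RF and baseband
#' I/Q samples are signed and zero-mean. The zigzag bijection
#' `0 -> 1, 1 -> 2, -1 -> 3, 2 -> 4, ...` interleaves signs so that small
#' magnitudes — the bulk of speckle-dominated data — receive short codewords.
#'
#' @param v signed integer vector.
#' @param Z positive integer vector.
#' @return `zigzag_map()`: positive integers; `zigzag_unmap()`: the original
#'   signed values.
#' @examples
#' zigzag_map(c(0, 1, -1, 2, -5))   # 1 2 3 4 11
#' zigzag_unmap(zigzag_map(-7:7))
#' @export
zigzag_map <- function(v) {
  v <- as.numeric(v)
  ifelse(v >= 0, 2 * v + (v == 0), 1 - 2 * v)
}

#' @rdname zigzag_map
#' @export
zigzag_unmap <- function(Z) {
  Z <- check_positive(Z, "Z")
  ifelse(Z == 1, 0, ifelse(Z %% 2 == 0, Z / 2, (1 - Z) / 2))
}

#' Lossless frame compression into a self-describing container
#'
#' Samples are flattened row-major (depth-first, matching per-scanline
#' acquisition order), zigzag-mapped to positive integers, and encoded as one
#' concatenated codeword stream. The container header records coder, `S`,
#' mapping, bit depth, stage, dimensions, sampling rate, and the exact payload
#' bit count, so decompression is bit-exact with no side information.
#'
#' @param frame a [sample_frame()].
#' @param coder one of `"bl"`, `"exp-golomb"`, `"elias-gamma"`,
#'   `"elias-delta"`, `"fibonacci"`.
#' @param S BL suffix parameter (stored but only meaningful for `coder =
#'   "bl"`).
#' @return object of class `bl_container`.
#' @examples
#' fr <- sample_frame(matrix(0L, 4, 4), bit_depth = 16)
#' ct <- compress_frame(fr)
#' compression_ratio(frame_bits(fr), ct$payload_bits)  # 81.25
#' @export
compress_frame <- function(frame, coder = "bl", S = 1) {
  stopifnot(inherits(frame, "sample_frame"))
  coder <- check_coder(coder)
  S <- check_S(S)
  check_frame_range(frame$samples, frame$bit_depth)
  v <- as.vector(t(frame$samples))      # row-major flattening
  z <- zigzag_map(v)
  bits <- encode_values_bits(z, coder, S)
  structure(list(
    version = 1L,
    coder = coder,
    S = as.integer(S),
    mapping = "zigzag",
    bit_depth = frame$bit_depth,
    stage = frame$stage,
    rows = nrow(frame$samples),
    cols = ncol(frame$samples),
    sampling_rate = frame$sampling_rate,
    payload_bits = as.numeric(length(bits)),
    payload = pack_bits(bits)
  ), class = "bl_container")
}

#' @export
print.bl_container <- function(x, ...) {
  raw_bits <- x$rows * x$cols * x$bit_depth
  cat(sprintf(
    "<bl_container v%d: %d x %d %s, %d-bit, coder %s (S=%d)>\n",
    x$version, x$rows, x$cols, x$stage, x$bit_depth, x$coder, x$S))
  cat(sprintf("  payload %d bits (%.2f%% compression vs %d raw bits)\n",
              x$payload_bits, compression_ratio(raw_bits, x$payload_bits),
              raw_bits))
  invisible(x)
}

#' Decompress a container back to the original frame
#'
#' Exact inverse of [compress_frame()]: decodes `rows * cols` codewords,
#' inverts the zigzag mapping, and restores the row-major sample grid with its
#' stage, bit depth, and sampling rate. A malformed container raises a
#' distinct error: `blcodec_bad_magic` for a corrupt file tag,
#' `blcodec_bad_version` for an unknown version, `blcodec_truncated` for a
#' short payload, `blcodec_symbol_count` for a payload whose codewords do not
#' tile its bit count exactly.
#'
#' @param container a `bl_container`, from [compress_frame()] or [read_blc()].
#' @return the original [sample_frame()].
#' @export
decompress_frame <- function(container) {
  stopifnot(inherits(container, "bl_container"))
  if (container$version != 1L)
    stop(errorCondition(
      sprintf("unsupported container version %d", container$version),
      class = c("blcodec_bad_version", "blcodec_error")))
  if (container$mapping != "zigzag")
    stop(errorCondition("unknown sample mapping",
                        class = c("blcodec_bad_mapping", "blcodec_error")))
  n <- container$rows * container$cols
  bits <- unpack_bits(container$payload, container$payload_bits)
  dec <- decode_values_bits(bits, n, container$coder, container$S)
  if (dec$bits_consumed != container$payload_bits)
    stop(errorCondition(
      sprintf("payload bit count mismatch: %d declared, %d consumed",
              container$payload_bits, dec$bits_consumed),
      class = c("blcodec_symbol_count", "blcodec_error")))
  v <- zigzag_unmap(dec$values)
  samples <- matrix(as.integer(v), nrow = container$rows,
                    ncol = container$cols, byrow = TRUE)
  sample_frame(samples, stage = container$stage,
               bit_depth = container$bit_depth,
               sampling_rate = container$sampling_rate)
}

#' Compression ratio and relative improvement
#'
#' `compression_ratio()` is `(1 - compressed/uncompressed) * 100` percent
#' (negative when the coder expands the data). `relative_improvement()` is
#' `(baseline - proposed)/baseline * 100`, the same arithmetic applied to two
#' compressed sizes; the two functions agree argument for argument.
#'
#' @param uncompressed_bits,baseline_bits reference size in bits (> 0).
#' @param compressed_bits,proposed_bits achieved size in bits.
#' @return percentage.
#' @examples
#' compression_ratio(100, 70)      # 30
#' relative_improvement(13, 10)    # 23.07692
#' @export
compression_ratio <- function(uncompressed_bits, compressed_bits) {
  if (any(uncompressed_bits <= 0))
    stop("uncompressed size must be positive", call. = FALSE)
  (1 - compressed_bits / uncompressed_bits) * 100
}

#' @rdname compression_ratio
#' @export
relative_improvement <- function(baseline_bits, proposed_bits) {
  if (any(baseline_bits <= 0))
    stop("baseline size must be positive", call. = FALSE)
  (baseline_bits - proposed_bits) / baseline_bits * 100
}

#' @rdname compression_ratio
#' @param frame a [sample_frame()].
#' @return `frame_bits()`: uncompressed size in bits (samples times declared
#'   bit depth).
#' @export
frame_bits <- function(frame) {
  stopifnot(inherits(frame, "sample_frame"))
  nrow(frame$samples) * ncol(frame$samples) * frame$bit_depth
}

# --- container serialisation -------------------------------------------------
# Layout (little-endian): magic "BLUC" (4) | version (1) | coder id (1) |
# S (1) | mapping id (1) | bit depth (1) | stage id (1) | rows (u32) |
# cols (u32) | sampling rate (f64) | payload bit count (u64) | payload bytes.

u_to_raw <- function(x, nbytes) as.raw((x %/% 256^(0:(nbytes - 1))) %% 256)
raw_to_u <- function(r) sum(as.numeric(r) * 256^(seq_along(r) - 1))

#' Read and write the `.blc` container format
#'
#' A byte-exact, versioned on-disk form of [compress_frame()]'s output. All
#' multi-byte header fields are little-endian.
#'
#' @param container a `bl_container`.
#' @param path file path.
#' @return `read_blc()`: a `bl_container`; `write_blc()`: `path`, invisibly.
#' @export
write_blc <- function(container, path) {
  stopifnot(inherits(container, "bl_container"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BLUC"), con)
  writeBin(as.raw(c(container$version, CODER_IDS[[container$coder]],
                    container$S, 1L, container$bit_depth,
                    STAGE_IDS[[container$stage]])), con)
  writeBin(u_to_raw(container$rows, 4L), con)
  writeBin(u_to_raw(container$cols, 4L), con)
  writeBin(as.numeric(container$sampling_rate), con, size = 8,
           endian = "little")
  writeBin(u_to_raw(container$payload_bits, 8L), con)
  writeBin(container$payload, con)
  invisible(path)
}

#' @rdname write_blc
#' @export
read_blc <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 34L || !identical(rawToChar(r[1:4]), "BLUC"))
    stop(errorCondition("not a BLUC container (bad magic)",
                        class = c("blcodec_bad_magic", "blcodec_error")))
  version <- as.integer(r[5])
  if (version != 1L)
    stop(errorCondition(sprintf("unsupported container version %d", version),
                        class = c("blcodec_bad_version", "blcodec_error")))
  coder_id <- as.integer(r[6])
  coder <- names(CODER_IDS)[match(coder_id, CODER_IDS)]
  if (is.na(coder))
    stop(errorCondition("unknown coder id",
                        class = c("blcodec_bad_coder", "blcodec_error")))
  stage_id <- as.integer(r[10])
  stage <- names(STAGE_IDS)[match(stage_id, STAGE_IDS)]
  if (is.na(stage))
    stop(errorCondition("unknown stage id",
                        class = c("blcodec_bad_stage", "blcodec_error")))
  rows <- as.integer(raw_to_u(r[11:14])); cols <- as.integer(raw_to_u(r[15:18]))
  srate <- readBin(r[19:26], "double", size = 8, endian = "little")
  payload_bits <- raw_to_u(r[27:34])
  payload <- r[-(1:34)]
  if (length(payload) < ceiling(payload_bits / 8))
    stop(errorCondition("container payload is truncated",
                        class = c("blcodec_truncated", "blcodec_error")))
  structure(list(version = version, coder = coder, S = as.integer(r[7]),
                 mapping = "zigzag", bit_depth = as.integer(r[9]),
                 stage = stage, rows = rows, cols = cols,
                 sampling_rate = srate, payload_bits = payload_bits,
                 payload = payload),
            class = "bl_container")
}

#' Read and write raw little-endian int16 sample files
#'
#' The common ADC container: samples stored row-major as little-endian signed
#' 16-bit words regardless of the declared bit depth, which is validated on
#' read.
#'
#' @param path file path.
#' @param rows,cols frame dimensions; `rows * cols` must match the file size.
#' @inheritParams sample_frame
#' @param frame a [sample_frame()] (for writing).
#' @return `read_frame_i16()`: a [sample_frame()]; `write_frame_i16()`:
#'   `path`, invisibly.
#' @export
read_frame_i16 <- function(path, rows, cols, stage = "pre-beamformed",
                           bit_depth = 12, sampling_rate = 40e6) {
  nbytes <- file.size(path)
  if (is.na(nbytes) || nbytes != 2 * rows * cols)
    stop(sprintf("file size %s does not match %d x %d int16 samples",
                 format(nbytes), rows, cols), call. = FALSE)
  v <- readBin(path, "integer", n = rows * cols, size = 2, signed = TRUE,
               endian = "little")
  sample_frame(matrix(v, nrow = rows, ncol = cols, byrow = TRUE),
               stage = stage, bit_depth = bit_depth,
               sampling_rate = sampling_rate)
}

#' @rdname read_frame_i16
#' @export
write_frame_i16 <- function(frame, path) {
  stopifnot(inherits(frame, "sample_frame"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(t(frame$samples)), con, size = 2, endian = "little")
  invisible(path)
}
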