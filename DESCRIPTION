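Package: blcodec
Title: Binary-Cluster Universal Codes and Lossless Ultrasound Frame Compression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encoders and decoders for the binary-cluster (BL) universal prefix
    code for positive integers, together with the classic baseline coders it is
    usually compared against (unary, order-0 exponential Golomb, Elias gamma,
    Elias delta, Fibonacci). Includes a bit-exact lossless codec for signed
    ultrasound sample frames (pre-beamformed RF, beamformed RF, baseband I/Q)
    built on a zigzag signed-to-positive mapping and a self-describing
    container format, a synthetic ultrasound frame generator emulating
    Rayleigh-distributed speckle with point targets and anechoic cysts, and a
    command-line interface for compression, code tables, and benchmark reports.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, signal
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
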