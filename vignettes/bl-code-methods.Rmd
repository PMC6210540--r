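---
title: "Methods: the BL universal code and the synthetic ultrasound testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the BL universal code and the synthetic ultrasound testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blcodec)
```

## The code family

A universal code maps positive integers to self-delimiting binary codewords
without knowledge of the source distribution. The BL code's prefix alphabet
is the set of *binary clusters* — patterns beginning with `10` and containing
no other `10` — indexed by a 1-based code-num $M$. Writing $K$ for the group
index (cluster bit length minus one), the enumeration satisfies

$$\frac{K(K-1)}{2} < M \le \frac{K(K+1)}{2},
\qquad X = M - \frac{K(K-1)}{2} \in \{1,\dots,K\},$$

and the cluster is `1`, then $K-(X-1)$ zeros, then $X-1$ ones. There are $K$
clusters of length $K+1$, so the prefix length grows like
$\sqrt{2M}$ — the essential advantage over the unary prefix of the
exponential Golomb code, whose length grows linearly in the group number.

Encoding an integer $Z \ge 1$ under the suffix parameter $S \ge 1$:

1. $M$ is the smallest integer with $Z \le 2^S(2^M - 1)$;
2. the prefix is the cluster for $M$, **reversed**, so that it terminates at
   its unique `01` pair;
3. the suffix is $Z - 2^S(2^{M-1}-1) - 1$ in exactly $M+S-1$ binary digits.

Values assigned to code-num $M$ form the contiguous block
$2^S(2^{M-1}-1)+1,\dots,2^S(2^M-1)$, which has $2^{M+S-1}$ elements — exactly
what the suffix width enumerates, for every $S \ge 1$. Decoding scans to the
first `01`, sets $K$ = prefix length − 1 and $T$ = number of leading ones,
recovers $M = K(K-1)/2 + T + 1$, then reads $M+S-1$ suffix bits and inverts
step 3. The package tests this range partition exhaustively for $M \le 12$
and the encode/decode identity for $Z \le 10^5$ at $S \in \{1,2,3\}$.

### Reading the published formulas

Two typeset ambiguities in the source material had to be resolved; both
resolutions are forced by internal consistency:

* The factor printed as "2S" in the encoding/decoding formulas is read as
  $2^S$ (the same flattening that renders $2^{M-1}$ as "2M−1"). Only this
  reading makes the $M+S-1$-bit suffix enumerate the value block exactly for
  every $S$; the two readings coincide at $S=1$, the only setting evaluated
  in the source.
* "The largest integer that is smaller than $X$" in the group-index formula
  is a *strict* floor (at integer $X$ it yields $X-1$); with the ordinary
  floor, $M = 1$ would give $K = 2$, contradicting the printed table.

Two printed cells are internally inconsistent and are corrected by the
formulas: the code table's entry for $Z=15$ shows a 7-bit codeword although
its own prefix (`0001`) and suffix (`0000`) columns concatenate to 8 bits —
the package encodes the 8-bit `00010000` and flags the discrepancy in
`verify_paper()` and the CLI table; and a sentence stating "$K$ and $X$ are 1
and 4" for $M=10$ is a typo for $K=4$ (the printed cluster `10111` has
$K=4$).

### Numerical choices

* `group_index()` and `code_num_for_value()` use integer search seeded by a
  floating-point estimate and corrected by exact comparisons, never a bare
  `sqrt`/`log2` + `ceiling`: float rounding at exact powers of two (e.g.
  $Z \in \{2, 6, 126\}$ at $S=1$) would otherwise shift the boundary. The
  equivalence with the strict-floor formula is tested for $M \le 10^6$.
* Arithmetic is exact IEEE-double integer arithmetic, valid below $2^{53}$;
  larger inputs raise an error rather than silently losing precision. This
  bounds codewords at roughly 63 bits, far beyond any ADC word.
* Bit packing is MSB-first (first bit written = highest bit of the first
  byte), matching left-to-right bit-string notation; the final byte is
  zero-padded, and decoders never read the padding — the symbol count in the
  container header terminates decoding, since padding `0…` could otherwise
  be misparsed as the start of a codeword.
* The abstract-level name "BL-beta" is not defined in the source body; the
  package exposes the parameter simply as `S` and takes no position beyond
  that.
* The code-num formula is introduced empirically in the source; the
  integer-comparison definition used here is verified exhaustively for
  $S = 1$ and by the range-partition property for the tested $S$; no claim
  is made beyond tested ranges.

## Baseline coders

Unary, order-0 exponential Golomb, Elias gamma, Elias delta, and Fibonacci
coders share the bitstream substrate. The comparison tables index the
exponential Golomb code from $Z=1 \mapsto$ `1`, i.e. the order-0 code of
$Z-1$; under this shift its codewords coincide bit-for-bit with Elias gamma
codewords of $Z$ — both entry points are kept because the constructions (and
their generalisations) differ. Fibonacci coding uses the Zeckendorf
representation over $F(2)=1, F(3)=2, \dots$ with an appended terminal `1`;
this indexing is the one consistent with the 30-bit length of the codeword
for 1,000,000, cross-checked against a brute-force Zeckendorf oracle before
the golden tests were frozen.

## The frame codec

Ultrasound RF and baseband I/Q samples are signed and zero-mean, while
universal codes are defined on positive integers. The codec therefore maps
samples through the zigzag bijection ($0\to1$, $v>0\to2v$, $v<0\to1-2v$),
chosen because it is magnitude-ordered: the Rayleigh-speckle argument — most
samples are small, so short codewords dominate — survives the mapping intact.
Frames are flattened row-major (depth-first, matching per-scanline
acquisition), encoded as one concatenated codeword stream, and stored in a
34-byte self-describing container (magic, version, coder, $S$, mapping, bit
depth, stage, dimensions, sampling rate, payload bit count). The compression
ratio $(1 - \text{compressed}/\text{uncompressed}) \times 100\%$ is computed
on payload bits only, consistent with the code's no-overhead streaming use;
the CLI additionally logs the with-header ratio. The uncompressed size is
samples × declared ADC bit depth (not the 16-bit storage container).

The lossless contract — `decompress_frame(compress_frame(x))` is bit-exact —
is tested on 50 random frames across bit depths 12/14/16 and on every
supported coder, and corrupt containers fail with distinct error classes
(bad magic, bad version, truncation, symbol-count mismatch) rather than
returning wrong samples.

## The synthetic testbed

The generator emulates the *distributional* features the codec responds to,
not image formation:

* **Speckle.** Per column, white Gaussian scatterers are convolved with a
  Gaussian-windowed sinusoid (centre frequency 8 MHz, sampling rate 40 MHz,
  fractional −6 dB bandwidth 0.6 — a typical linear array; only centre
  frequency and sampling rate are given by the source). A filtered Gaussian
  process is Gaussian, so the envelope of homogeneous regions is Rayleigh;
  the test suite checks a Kolmogorov–Smirnov distance below 0.02 against a
  fitted Rayleigh at $n = 10^5$ envelope samples, computed on interior rows
  (filter edges taper and would contaminate the sample).
* **Structure.** Point targets add scaled pulse echoes in their column; cysts
  multiply scatterer strength by an echogenicity in $[0,1]$ inside a circle.
* **Stages.** "Beamformed" frames are coherent sums of 8 adjacent channels —
  amplitude grows like $\sqrt{8}$ for diffuse speckle — rather than true
  delay-and-sum with geometry, because the codec consumes amplitude
  statistics only. I/Q is produced by mixing with $\cos/-\sin$ at the
  carrier (no mixer gain, so in-band amplitude halves, as in analog
  front-end chips), low-pass filtering with a 64-tap linear-phase
  windowed-sinc FIR (`signal::fir1`) cut at half the decimated Nyquist, row
  decimation (default 4), and re-quantisation. Samples are rounded and
  clipped to the configured bit depth; the clipped fraction is reported as an
  attribute and asserted below 0.1% at default amplitudes.

Default amplitudes were chosen once, from the physics the source describes,
to emulate its acquisition regimes: quiet phantom backgrounds at RMS 12 ADC
units on a 12-bit scale, tissue-like frames at RMS 20–22 with low-contrast
hypoechoic structure (denser, brighter speckle compresses worse — the in
vitro/in vivo contrast). These choices put baseband I/Q compression in the
20–40% range the source reports as the code's stable operating band. Frame
defaults are 2048 × 128 for the standalone generator; the benchmark suite
uses 1024 × 64 pre-beamformed frames (the source does not state its frame
dimensions; these keep a full 4-dataset × 4-stage × 2-coder benchmark around
a second).

### What passing tests do and do not show

The original in vitro/in vivo acquisitions are not public, so their absolute
compression ratios (e.g. 41.2% pre-beamformed point targets) are not
reproduction targets. The suite instead asserts the *structure* those numbers
exhibit: BL strictly beats exponential Golomb on mean I/Q ratio; phantom
frames out-compress tissue-like frames at the pre-beamformed stage; I and Q
ratios agree within one percentage point (identical amplitude, π/2 phase
shift); baseband I/Q compresses at least as well as beamformed RF; and the
BL ratio on tissue-like I/Q frames stays inside a broad 15–45% sanity band
across 10 seeds. Passing these says the codec behaves correctly on data with
the right amplitude statistics; it does not certify absolute ratios on any
particular scanner's data, which depend on gain staging, TGC, and tissue.

The generator also omits attenuation/TGC, scan conversion, true array
geometry, and electronic noise floors; none of these change what the codec
is being tested for (lossless correctness and magnitude-driven code-length
behaviour), but absolute ratios on real acquisitions will differ.

## Known limitations

* Values at or above $2^{53}$ are rejected (no big-integer backend).
* One $S$ per stream; no adaptive or per-datum parameter selection.
* No run-length preprocessing, inter-frame prediction, or lossy modes.
* Decoding is inherently sequential; the implementation amortises it with a
  two-pass vectorised design but makes no real-time throughput claims.
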