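# blcodec

Lossless compression of medical ultrasound data with the binary-cluster (BL)
universal code.

Software-based ultrasound imaging systems move raw sensor data from the
transducer front end to a general-purpose host, and the required transfer
rate — 128 channels × 40 MHz × 12 bits is 10 GB/s — is the bottleneck that
keeps portable systems off commodity links such as USB 3.0. Because
per-channel RF and baseband I/Q samples are speckle-dominated (Rayleigh
envelope statistics), most samples are small in magnitude, and a
variable-length *universal code* — a prefix-free map from positive integers to
binary codewords — compresses them losslessly in real time with no
dictionaries, no side tables, and no per-block overhead.

This package is for engineers and researchers working on ultrasound data
paths (and anyone who needs fast variable-length integer codes): it provides
the BL code, the baselines it is compared against, a bit-exact frame codec,
and a synthetic speckle-frame generator so the whole pipeline runs without
acquired data.

## The BL code

A **binary cluster** is a bit pattern that starts with `10` and contains no
second `10`; enumerated in order (`10`, `100`, `101`, `1000`, `1001`,
`1011`, …) the M-th cluster has length K + 1, where the group index K is the
unique integer with

    K(K−1)/2 < M ≤ K(K+1)/2,

and the position within the group is X = M − K(K−1)/2. The cluster is the MSB
`1` followed by K − (X − 1) zeros and X − 1 ones. The BL codeword for an
integer Z ≥ 1 under parameter S ≥ 1 is

* **prefix** — the cluster for code-num M, *reversed*, so it ends at its
  unique `01` pair and the code is instantaneously decodable; M is the
  smallest integer with Z ≤ 2^S (2^M − 1);
* **suffix** — the offset Z − 2^S (2^(M−1) − 1) − 1 in exactly M + S − 1
  binary digits.

Total length K + M + S. Decoding scans to the first `01` (giving K and the
leading-ones count T), recovers M = K(K−1)/2 + T + 1, reads M + S − 1 suffix
bits, and inverts the offset. Because the prefix grows like the inverse
triangular root of M instead of linearly (as the unary prefix of the
exponential Golomb code does), large integers get much shorter codewords:
1,000,000 encodes in 26 bits versus 39 (exponential Golomb or Elias gamma),
30 (Fibonacci), and 28 (Elias delta).

Signed samples enter the integer coders through the zigzag bijection
0→1, 1→2, −1→3, 2→4, …, which preserves the small-magnitude → short-codeword
property that the Rayleigh amplitude statistics reward.

## Worked example

```r
library(blcodec)

code_table(10)[c(1, 2, 7, 10), ]
#>     Z golomb_prefix golomb_suffix golomb_code bl_prefix bl_suffix bl_code
#> 1   1             1                         1        01         0     010
#> 2   2            01             0         010        01         1     011
#> 7   7           001            11       00111       101       000  101000
#> 10 10          0001           010     0001010       101       011  101011

bl_encode(1000000)
#> [1] "11100011110100001001000001"       # 26 bits

bs <- bl_encode_sequence(c(100, 1024)) # no separators, no overhead
bl_decode_sequence(bs, 2)
#> [1]  100 1024

fr <- generate_rf_frame(phantom_config(rows = 1024, cols = 64, seed = 1))
compress_frame(fr)
#> <bl_container v1: 1024 x 64 pre-beamformed, 12-bit, coder bl (S=1)>
#>   payload 514119 bits (34.63% compression vs 786432 raw bits)
```

The codeword table rows read: integer `Z`, then prefix/suffix/codeword for
the order-0 exponential Golomb code and for the BL code. The container line
reports the payload size produced by the codec and the percentage compression
ratio `(1 − compressed/uncompressed) × 100` against the declared 12-bit
sample width.

A benchmark over the built-in synthetic suite (two phantom-like and two
tissue-like data sets, each as pre-beamformed RF, beamformed RF, and baseband
I/Q) reproduces the qualitative structure reported for acquired data — BL
beats exponential Golomb at every stage, and baseband I/Q compresses better
than beamformed RF:

```r
run_benchmark(seed = 1)$means
#>            stage      coder    ratio
#> 1     beamformed         bl 28.40449
#> 2              I         bl 41.10819
#> 3 pre_beamformed         bl 42.40236
#> 4              Q         bl 41.26485
#> 5     beamformed exp-golomb 14.05233
#> 6              I exp-golomb 34.54386
#> 7 pre_beamformed exp-golomb 36.64633
#> 8              Q exp-golomb 34.81445
```

## Command line

An `exec/blcodec` script exposes the same operations from a shell:

```sh
blcodec table --zmax 16
blcodec compress --input frame.i16 --rows 1024 --cols 64 --bit-depth 12 --output frame.blc
blcodec decompress --input frame.blc --output restored.i16
blcodec verify-paper          # exit 0 iff all golden examples reproduce
blcodec bench --seed 1 --out report.tsv
blcodec generate --dataset cyst_phantom --stage I --output cyst_I.i16
```

Exit codes: 0 success, 2 format/usage error, 3 verification failure.

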