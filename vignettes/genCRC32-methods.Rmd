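---
title: "genCRC32: methods, design choices and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{genCRC32: methods, design choices and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genCRC32)
```

## The problem

Hash-based k-mer data structures — de Bruijn graph assemblers, k-mer
stores, taxonomic classifiers, sketching indices — suffer when distinct
k-mers map to the same hash value. A 32-bit output space can in principle
hold all $4^{16} \approx 2^{32}$ 16-mers injectively, but general-purpose
hash functions come nowhere near that bound in practice: collisions appear
from $k = 9$–$12$ onward under exhaustive enumeration. genCRC32 is a
deterministic scheme that reaches the bound: a nibble-packing
preprocessing step (gen32) followed by a reflected CRC32 with one of eight
specific polynomials is a bijection-grade (collision-free) map of every
complete $4^k$ k-mer space for $4 \le k \le 16$.

## The gen32 preprocessing step

Each nucleotide's ASCII byte is masked with `0x0E`, which isolates bits
1–3 — the bits that happen to differ uniquely among A/a, C/c, G/g and T/t:

| base | ASCII (upper/lower) | code |
|------|---------------------|------|
| A/a  | 0x41 / 0x61         | 0x0  |
| C/c  | 0x43 / 0x63         | 0x2  |
| G/g  | 0x47 / 0x67         | 0x6  |
| T/t  | 0x54 / 0x74         | 0x4  |

so no explicit case normalization is ever needed. Consecutive codes are
packed two per byte (shift the byte left four bits, OR in the new code),
giving $\lceil k/2 \rceil$ bytes; for odd $k$ the final lone code sits in
the low nibble of the last byte. The masking trick is injective *only* on
the four nucleotides — `encodeNibble("N")` would alias a real base — so
the package rejects non-ACGT input by default. A `strict = FALSE`
escape hatch exists purely for benchmarking parity with hash functions
applied to raw bytes.

```{r}
gen32Pack("ACGT")            # 0x02 0x64
identical(gen32Pack("acgt"), gen32Pack("ACGT"))
```

## Reflected CRC32 and the register convention

All twenty candidate polynomial constants are interpreted as
**reversed-form (LSB-first) divisors** fed to the standard table-driven
reflected CRC32 with `init = xorOut = 0xFFFFFFFF` — the convention of the
ubiquitous standard-library CRC32 (`crc32("123456789", "0xEDB88320")`
yields the canonical check value `0xCBF43926`). This is the single most
reproducibility-critical choice in the package: the constants alone do
not pin down a CRC. It is validated end to end — under this convention
the audits reproduce the published collision-onset structure exactly, for
every one of the twenty polynomials, which would not survive a wrong
register convention. Odd-looking constants (`0xA3000000`,
`0xAD0424F3`, ...) are deliberately passed through unmodified.

`gencrc32(x) = crc32(gen32Pack(x))` is exposed as `genCrc32()`, and
`HashConfig` objects name every benchmarked combination of
preprocessing (`none` = uppercase ASCII bytes, `gen32` = packed bytes)
and family (`crc32`, `murmur3_32`, `xxhash32`). MurmurHash3-32 and
xxHash32 are compiled from their public reference algorithms and pinned
by frozen test vectors; their seeds default to 0 (the upstream library
defaults) and are recorded in the configuration label, because collision
onsets of seeded hashes are seed-dependent.

## Exhaustive collision audits

`countCollisions()` hashes the complete $4^k$ space (enumerated
arithmetically in C++, never materializing strings) and counts distinct
outputs with one of two backends:

* **sort** — fill a `uint32` array, sort, count unique; simple and fast,
  bounded to $k \le 13$ (268 MB at the bound);
* **bitset** — a 512 MB occupancy bitset over the whole 32-bit output
  space, streaming chunks whose processing order can be shuffled;
  memory-bounded for $k$ up to 16.

The two backends are required by the test suite to agree wherever both
run. Replicated audits (`replicateAudit()`) re-run the bitset backend
with shuffled chunk order: distinct-value counting is order-free, so all
replicates must agree exactly, and `consistent = FALSE` would flag
nondeterminism as an error condition rather than averaging it away.
Audits at $k > 13$ are refused unless forced (hours of work at $k = 16$),
and $k > 16$ is refused outright: with $4^k > 2^{32}$ inputs injectivity
is impossible by pigeonhole.

## An exact injectivity certificate

The audits are the ground truth, but for gen32+CRC32 the package also
carries an exact algebraic certificate (`crcInjectivityRank()`). Two
facts combine:

1. a CRC is affine over GF(2): the XOR of two outputs equals the
   init-free CRC of the XOR of the (equal-length) inputs;
2. the per-position difference set of gen32 nibble codes,
   $\{0x0, 0x2, 0x4, 0x6\}$, is itself a linear subspace of dimension 2.

Hence the difference of any two packed k-mers lies in the span of $2k$
single-bit basis deltas, and the scheme is collision-free on the complete
space **iff** the CRC images of those $2k$ basis deltas are linearly
independent — a rank computation over GF(2) that runs in microseconds
and is exact even at $k = 16$, where the exhaustive audit needs
$4^{16}$ hashes. The test suite proves the certificate against the
audits on every desk-scale configuration, then uses it to certify the
full $k = 16$ claim for the eight selected polynomials:

```{r}
hex32(screenPolynomials(crcPolynomials(), kMax = 16, method = "rank"))
```

Note the certificate covers CRC configurations only; MurmurHash3 and
xxHash32 are nonlinear, and their onsets are established by audit alone.

## Bucket-occupancy uniformity

Collision-freeness says nothing about how evenly values fill a hash
table. `uniformityPanel()` buckets hashes as $h \bmod m$ over a panel of
bucket counts spanning typical table sizes — powers of two and nearby odd
primes, default $\{64, 67, 256, 257, 1021, 1024, 4093, 4096, 16381,
16384, 65521, 65536\}$ — and scores each against the uniform expectation
$n/m$ with Pearson's $\chi^2$ on $m - 1$ degrees of freedom. Bucketings
with expected count $n/m \le 5$ are suppressed, not reported, since the
$\chi^2$ approximation is invalid there. One dataset-level summary is
reported as the **median** of the admissible $p$ values: a panel must be
collapsed somehow, the median is order-statistic-stable, and the full
per-$m$ table is always emitted alongside so nothing is hidden by the
aggregation rule.

## Avalanche (mean flip)

`avalanche()` quantifies diffusion under the smallest biologically
meaningful perturbation: for each origin k-mer it draws three independent
single-base substitutions (position uniform over $k$, replacement uniform
over the three alternatives), hashes origin and mutant, and averages the
fraction of the 32 output bits flipped. Ideal diffusion is 0.5.

For CRC configurations the affine property gives an exact, sample-free
value: the flip fraction of a pair depends only on the XOR-delta of the
preprocessed inputs, so the mean over the protocol is a finite average
over $k$ positions $\times$ 3 deltas (gen32) or 6 ASCII deltas (raw).
`exactCrcMeanFlip()` computes it directly and serves as the analytic
oracle the Monte Carlo estimate must match within Monte Carlo error:

```{r}
exactCrcMeanFlip("0x8741C726", 16)           # gen32, ~0.484
exactCrcMeanFlip("0x8741C726", 16, "none")   # raw ASCII, ~0.503
exactCrcMeanFlip("0x8EFD4BCD", 16)           # ~0.454
```

The slight sub-0.5 bias of some gen32 configurations is real, not
sampling noise: only 6 of the 8 bits per packed byte ever vary, so the
reachable delta space is a $2k$-dimensional subspace rather than the
full message space, and nothing forces its CRC images to average exactly
half the bits.

## Workload generators

Three regimes emulate common k-mer workloads, each fully reproducible
from a seed and shared across all configurations under comparison so
that hashing behavior is isolated from input composition:

* **random** — i.i.d. uniform bases; the reference workload and the
  origin set for avalanche measurement;
* **similar** — a chain where each k-mer is a single-base edit of its
  predecessor, a worst case for locality-sensitive schemes; duplicates
  are kept (they are a property of the workload, not a key set);
* **window** — step-1 sliding windows over a genome, skipping windows
  containing non-ACGT characters and never spanning records.

The window regime defaults to a synthetic i.i.d. genome
(`syntheticGenome()`, 4.6 Mb at GC 0.508, echoing the *E. coli* K-12
MG1655 chromosome) so that no download is required; any real FASTA can
be substituted. The synthetic stand-in reproduces length and GC
composition but **not** the repeat structure, codon bias or oligomer
autocorrelation of a real genome, so window-regime uniformity results on
it demonstrate the machinery rather than the field behavior on real
sequence; collision audits are unaffected, as they run only on
exhaustive enumerations, never on generated workloads.

## Numerical and interface choices

* 32-bit values cross the R boundary as doubles (exact for integers up
  to $2^{53}$); hex helpers (`hex32`, `parseHex32`) avoid base R's
  signed 32-bit limits.
* All randomness flows through R's RNG under caller-supplied seeds;
  C++ code never draws random numbers, so every dataset, mutant set and
  shuffled audit is bit-reproducible from its seed.
* Mutants always differ from the origin (the replacement excludes the
  original base), making "Hamming distance exactly 1" an invariant
  rather than an expectation.
* Enumeration chunk size defaults to $2^{22}$ k-mers, keeping packed
  blocks under 64 MB; audit results are chunk-size-invariant by
  construction and by test.
* The test suite audits complete spaces up to $k = 12$ (about 22 million
  k-mers per configuration) and measures avalanche on $10^5$ origins;
  the acceptance script uses $10^6$ origins with three mutants each.
  These sizes keep a full run in minutes on one core while leaving the
  Monte Carlo error an order of magnitude below the two-decimal
  reporting precision.

## Limitations

* The collision-free property is for $k \le 16$ and 32-bit outputs;
  beyond that the pigeonhole principle applies and the package refuses
  to audit.
* The eight surviving polynomials are an empirical (now
  algebraically certified) selection; no closed-form characterization of
  *why* these divisors achieve full rank at $k = 16$ is offered, and
  other untested polynomials may share the property.
* Throughput numbers are hardware- and build-dependent; the package
  measures them for orientation (`measureThroughput()`) but never
  asserts or compares them against published figures.
* Reverse-complement canonicalization is deliberately out of scope: the
  scheme hashes the forward strand as given.
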