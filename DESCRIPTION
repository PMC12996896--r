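Package: genCRC32
Title: Collision-Free CRC32 Hashing of DNA k-mers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements genCRC32, a 32-bit hashing scheme for DNA k-mers that
    combines a nibble-packing preprocessing step (gen32) with table-driven
    reflected CRC32 over selectable polynomials, achieving collision-free
    hashing of all 4^k k-mers up to k = 16 for eight identified polynomials.
    Provides the full evaluation battery: exhaustive collision audits over
    complete k-mer spaces (sort-unique and bitset backends), polynomial
    screening with an exact GF(2)-rank injectivity certificate,
    bucket-occupancy uniformity via Pearson chi-squared tests, avalanche
    (mean bit-flip) measurement with an exact linearity-derived oracle,
    reference 32-bit MurmurHash3 and xxHash32 comparators, and generators
    for random, similar-chain and sliding-window k-mer workloads including
    a synthetic genome stand-in.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, Rcpp, jsonlite, Biostrings
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
biocViews: Software, Alignment, Sequencing, DataRepresentation
RoxygenNote: 7.3.3
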