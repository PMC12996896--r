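#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>
#include "hash_core.h"

using namespace Rcpp;
using namespace gencrc32;

// All 32-bit values cross the R boundary as doubles (exact up to 2^53).

static HashSpec make_spec(int family, int prep, double poly, double init,
                          double xorout, double seed) {
  HashSpec s;
  s.family = family;
  s.prep = prep;
  s.init = (uint32_t)init;
  s.xorout = (uint32_t)xorout;
  s.seed = (uint32_t)seed;
  if (family == FAM_CRC32) crc_build_table((uint32_t)poly, s.table);
  return s;
}

// Validate one k-mer string into a digit buffer; 1-based error positions.
static void kmer_digits(const char* s, int k, uint8_t* digits, bool strict,
                        R_xlen_t which) {
  const uint8_t* tab = base_digit_table();
  for (int i = 0; i < k; ++i) {
    uint8_t d = tab[(uint8_t)s[i]];
    if (d == 0xFF) {
      if (strict)
        stop("k-mer %ld: invalid base '%c' at position %d (expected A/C/G/T)",
             (long)(which + 1), s[i], i + 1);
      d = 0;  // placeholder; permissive callers hash raw bytes instead
    }
    digits[i] = d;
  }
}

// [[Rcpp::export]]
NumericVector cpp_crc_table(double poly) {
  uint32_t table[256];
  crc_build_table((uint32_t)poly, table);
  NumericVector out(256);
  for (int i = 0; i < 256; ++i) out[i] = (double)table[i];
  return out;
}

// [[Rcpp::export]]
double cpp_crc32_raw(RawVector data, double poly, double init, double xorout) {
  uint32_t table[256];
  crc_build_table((uint32_t)poly, table);
  return (double)crc_hash(table, (uint32_t)init, (uint32_t)xorout,
                          RAW(data), (size_t)data.size());
}

// [[Rcpp::export]]
double cpp_murmur3_raw(RawVector data, double seed) {
  return (double)murmur3_32(RAW(data), (size_t)data.size(), (uint32_t)seed);
}

// [[Rcpp::export]]
double cpp_xxhash32_raw(RawVector data, double seed) {
  return (double)xxhash32(RAW(data), (size_t)data.size(), (uint32_t)seed);
}

// [[Rcpp::export]]
IntegerVector cpp_encode_nibble(CharacterVector bases, bool strict) {
  const uint8_t* tab = base_digit_table();
  R_xlen_t n = bases.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(bases, i));
    if (s[0] == '\0' || s[1] != '\0')
      stop("element %ld: expected a single character", (long)(i + 1));
    uint8_t c = (uint8_t)s[0];
    if (strict && tab[c] == 0xFF)
      stop("element %ld: invalid base '%c' at position 1 (expected A/C/G/T)",
           (long)(i + 1), s[0]);
    out[i] = (int)(c & 0x0E);
  }
  return out;
}

// [[Rcpp::export]]
RawVector cpp_gen32_pack(std::string kmer, bool strict) {
  int k = (int)kmer.size();
  if (k < 1) stop("empty sequence");
  if (k > 64) stop("sequence longer than 64 bases");
  uint8_t digits[64], packed[32];
  if (strict) {
    kmer_digits(kmer.c_str(), k, digits, true, 0);
    pack_digits(digits, k, packed);
  } else {
    // permissive: mask raw bytes without alphabet checks
    int size = (k + 1) / 2;
    std::memset(packed, 0, (size_t)size);
    for (int i = 0; i < k; ++i)
      packed[i >> 1] = (uint8_t)((packed[i >> 1] << 4)
                                 | ((uint8_t)kmer[i] & 0x0E));
  }
  RawVector out((k + 1) / 2);
  std::memcpy(RAW(out), packed, (size_t)out.size());
  return out;
}

// [[Rcpp::export]]
RawMatrix cpp_gen32_pack_batch(CharacterVector kmers, bool strict) {
  R_xlen_t n = kmers.size();
  if (n == 0) stop("empty input");
  int k = (int)LENGTH(STRING_ELT(kmers, 0));
  if (k < 1 || k > 64) stop("k must be in 1..64");
  int size = (k + 1) / 2;
  RawMatrix out(size, n);
  uint8_t digits[64];
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP s = STRING_ELT(kmers, i);
    if (LENGTH(s) != k) stop("k-mer %ld: mixed lengths in batch", (long)(i + 1));
    const char* p = CHAR(s);
    uint8_t* col = RAW(out) + (size_t)i * size;
    if (strict) {
      kmer_digits(p, k, digits, true, i);
      pack_digits(digits, k, col);
    } else {
      std::memset(col, 0, (size_t)size);
      for (int j = 0; j < k; ++j)
        col[j >> 1] = (uint8_t)((col[j >> 1] << 4) | ((uint8_t)p[j] & 0x0E));
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_hash_batch(CharacterVector kmers, int family, int prep,
                             double poly, double init, double xorout,
                             double seed, bool strict) {
  HashSpec spec = make_spec(family, prep, poly, init, xorout, seed);
  R_xlen_t n = kmers.size();
  NumericVector out(n);
  if (n == 0) return out;
  int k = (int)LENGTH(STRING_ELT(kmers, 0));
  if (k < 1 || k > 64) stop("k must be in 1..64");
  uint8_t digits[64], scratch[64];
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP s = STRING_ELT(kmers, i);
    if (LENGTH(s) != k) stop("k-mer %ld: mixed lengths in batch", (long)(i + 1));
    kmer_digits(CHAR(s), k, digits, strict, i);
    out[i] = (double)hash_digits(spec, digits, k, scratch);
  }
  return out;
}

// Exhaustive audit over all 4^k k-mers; returns the distinct-hash count.
// backend 0: hash array + sort/unique (k <= 13); backend 1: 2^32-bit occupancy
// bitset, streaming chunks whose order can be shuffled (order_seed >= 0).
// [[Rcpp::export]]
double cpp_audit_distinct(int family, int prep, double poly, double init,
                          double xorout, double seed, int k, int backend,
                          double order_seed) {
  if (k < 1 || k > 16) stop("audit requires k in 1..16");
  HashSpec spec = make_spec(family, prep, poly, init, xorout, seed);
  uint64_t total = 1ULL << (2 * k);
  uint8_t digits[16], scratch[16];

  if (backend == 0) {
    if (k > 13) stop("sort backend limited to k <= 13; use the bitset backend");
    std::vector<uint32_t> h(total);
    for (uint64_t idx = 0; idx < total; ++idx) {
      index_to_digits(idx, k, digits);
      h[idx] = hash_digits(spec, digits, k, scratch);
    }
    std::sort(h.begin(), h.end());
    uint64_t distinct = total ? 1 : 0;
    for (uint64_t i = 1; i < total; ++i)
      if (h[i] != h[i - 1]) ++distinct;
    return (double)distinct;
  }

  // bitset over the full 32-bit output space (512 MB)
  std::vector<uint64_t> bits(1ULL << 26, 0ULL);
  const uint64_t chunk = 1ULL << 20;
  uint64_t nchunks = (total + chunk - 1) / chunk;
  std::vector<uint64_t> order(nchunks);
  for (uint64_t c = 0; c < nchunks; ++c) order[c] = c;
  if (order_seed >= 0) {
    std::mt19937_64 rng((uint64_t)order_seed);
    std::shuffle(order.begin(), order.end(), rng);
  }
  uint64_t distinct = 0;
  for (uint64_t ci = 0; ci < nchunks; ++ci) {
    uint64_t lo = order[ci] * chunk;
    uint64_t hi = std::min(lo + chunk, total);
    for (uint64_t idx = lo; idx < hi; ++idx) {
      index_to_digits(idx, k, digits);
      uint32_t h = hash_digits(spec, digits, k, scratch);
      uint64_t w = h >> 6;
      uint64_t m = 1ULL << (h & 63u);
      if (!(bits[w] & m)) { bits[w] |= m; ++distinct; }
    }
    Rcpp::checkUserInterrupt();
  }
  return (double)distinct;
}

// [[Rcpp::export]]
CharacterVector cpp_index_to_kmer(NumericVector idx, int k) {
  if (k < 1 || k > 16) stop("k must be in 1..16");
  double total = std::pow(4.0, k);
  R_xlen_t n = idx.size();
  CharacterVector out(n);
  char buf[17];
  buf[k] = '\0';
  uint8_t digits[16];
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = idx[i];
    if (ISNAN(v) || v < 0 || v >= total || v != std::floor(v))
      stop("index %ld out of range [0, 4^%d)", (long)(i + 1), k);
    index_to_digits((uint64_t)v, k, digits);
    for (int j = 0; j < k; ++j) buf[j] = (char)ASCII_BASE[digits[j]];
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_kmer_to_index(CharacterVector kmers) {
  R_xlen_t n = kmers.size();
  NumericVector out(n);
  uint8_t digits[64];
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP s = STRING_ELT(kmers, i);
    int k = LENGTH(s);
    if (k < 1 || k > 16) stop("k-mer %ld: length must be 1..16", (long)(i + 1));
    kmer_digits(CHAR(s), k, digits, true, i);
    uint64_t v = 0;
    for (int j = 0; j < k; ++j) v = (v << 2) | digits[j];
    out[i] = (double)v;
  }
  return out;
}

// Block [from, to) of the enumeration: ASCII strings (mode 0) or a packed
// raw matrix (mode 1).
// [[Rcpp::export]]
SEXP cpp_enumerate_block(int k, double from, double to, int mode) {
  if (k < 1 || k > 16) stop("k must be in 1..16");
  double total = std::pow(4.0, k);
  if (from < 0 || to > total || from > to) stop("block out of range");
  uint64_t lo = (uint64_t)from, hi = (uint64_t)to;
  R_xlen_t n = (R_xlen_t)(hi - lo);
  uint8_t digits[16];
  if (mode == 0) {
    CharacterVector out(n);
    char buf[17];
    buf[k] = '\0';
    for (uint64_t idx = lo; idx < hi; ++idx) {
      index_to_digits(idx, k, digits);
      for (int j = 0; j < k; ++j) buf[j] = (char)ASCII_BASE[digits[j]];
      out[(R_xlen_t)(idx - lo)] = buf;
    }
    return out;
  }
  int size = (k + 1) / 2;
  RawMatrix out(size, n);
  for (uint64_t idx = lo; idx < hi; ++idx) {
    index_to_digits(idx, k, digits);
    pack_digits(digits, k, RAW(out) + (size_t)(idx - lo) * size);
  }
  return out;
}

// Apply single-base substitutions: pos is 1-based position, alt in 1..3 picks
// among the three bases other than the original (in A<C<G<T order).
// [[Rcpp::export]]
CharacterVector cpp_mutate_kmers(CharacterVector kmers, IntegerVector pos,
                                 IntegerVector alt) {
  R_xlen_t n = kmers.size();
  if (pos.size() != n || alt.size() != n)
    stop("pos/alt must match the number of k-mers");
  const uint8_t* tab = base_digit_table();
  CharacterVector out(n);
  char buf[65];
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP s = STRING_ELT(kmers, i);
    int k = LENGTH(s);
    if (k < 1 || k > 64) stop("k-mer %ld: length must be 1..64", (long)(i + 1));
    const char* p = CHAR(s);
    int pj = pos[i], aj = alt[i];
    if (pj < 1 || pj > k) stop("k-mer %ld: position out of range", (long)(i + 1));
    if (aj < 1 || aj > 3) stop("k-mer %ld: alt must be in 1..3", (long)(i + 1));
    std::memcpy(buf, p, (size_t)k);
    buf[k] = '\0';
    uint8_t d0 = tab[(uint8_t)p[pj - 1]];
    if (d0 == 0xFF)
      stop("k-mer %ld: invalid base '%c' at position %d (expected A/C/G/T)",
           (long)(i + 1), p[pj - 1], pj);
    // the aj-th digit among {0,1,2,3} \ {d0}
    int d = aj - 1;
    if (d >= (int)d0) ++d;
    buf[pj - 1] = (char)ASCII_BASE[d];
    out[i] = buf;
  }
  return out;
}

// Near-neighbor chain: element 0 is `first`; element i+1 differs from element
// i at exactly one position (pos 1-based, alt in 1..3 as in cpp_mutate_kmers).
// [[Rcpp::export]]
CharacterVector cpp_similar_chain(std::string first, IntegerVector pos,
                                  IntegerVector alt) {
  int k = (int)first.size();
  if (k < 1 || k > 64) stop("k must be in 1..64");
  R_xlen_t n = pos.size() + 1;
  if (alt.size() != pos.size()) stop("pos/alt lengths differ");
  uint8_t digits[64];
  kmer_digits(first.c_str(), k, digits, true, 0);
  char buf[65];
  buf[k] = '\0';
  for (int j = 0; j < k; ++j) buf[j] = (char)ASCII_BASE[digits[j]];
  CharacterVector out(n);
  out[0] = buf;
  for (R_xlen_t i = 1; i < n; ++i) {
    int pj = pos[i - 1], aj = alt[i - 1];
    if (pj < 1 || pj > k) stop("step %ld: position out of range", (long)i);
    if (aj < 1 || aj > 3) stop("step %ld: alt out of range", (long)i);
    uint8_t d0 = digits[pj - 1];
    int d = aj - 1;
    if (d >= (int)d0) ++d;
    digits[pj - 1] = (uint8_t)d;
    buf[pj - 1] = (char)ASCII_BASE[d];
    out[i] = buf;
  }
  return out;
}

// Avalanche kernel: per origin i, hash the origin and m mutants defined by
// pos/alt (grouped by origin), returning the flipped-bit fraction per pair.
// [[Rcpp::export]]
NumericVector cpp_avalanche_flips(CharacterVector origins, IntegerVector pos,
                                  IntegerVector alt, int m, int family,
                                  int prep, double poly, double init,
                                  double xorout, double seed) {
  HashSpec spec = make_spec(family, prep, poly, init, xorout, seed);
  R_xlen_t n = origins.size();
  if (pos.size() != (R_xlen_t)n * m || alt.size() != (R_xlen_t)n * m)
    stop("pos/alt must have length n * mutants");
  if (n == 0) stop("empty input");
  int k = (int)LENGTH(STRING_ELT(origins, 0));
  if (k < 1 || k > 64) stop("k must be in 1..64");
  NumericVector out((R_xlen_t)n * m);
  uint8_t digits[64], scratch[64];
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP s = STRING_ELT(origins, i);
    if (LENGTH(s) != k) stop("k-mer %ld: mixed lengths", (long)(i + 1));
    kmer_digits(CHAR(s), k, digits, true, i);
    uint32_t h0 = hash_digits(spec, digits, k, scratch);
    for (int j = 0; j < m; ++j) {
      R_xlen_t t = i * m + j;
      int pj = pos[t], aj = alt[t];
      if (pj < 1 || pj > k) stop("pair %ld: position out of range", (long)(t + 1));
      if (aj < 1 || aj > 3) stop("pair %ld: alt out of range", (long)(t + 1));
      uint8_t d0 = digits[pj - 1];
      int d = aj - 1;
      if (d >= (int)d0) ++d;
      digits[pj - 1] = (uint8_t)d;
      uint32_t h1 = hash_digits(spec, digits, k, scratch);
      digits[pj - 1] = d0;
      uint32_t x = h0 ^ h1;
      int bits = 0;
      while (x) { x &= x - 1; ++bits; }
      out[t] = bits / 32.0;
    }
  }
  return out;
}

// Build k-mer strings from base digits (0..3), length n*k, row-major.
// [[Rcpp::export]]
CharacterVector cpp_digits_to_kmers(IntegerVector digits, int n, int k) {
  if ((R_xlen_t)n * k != digits.size()) stop("digit vector has wrong length");
  if (k < 1 || k > 64) stop("k must be in 1..64");
  CharacterVector out(n);
  char buf[65];
  buf[k] = '\0';
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) {
      int d = digits[(R_xlen_t)i * k + j];
      if (d < 0 || d > 3) stop("digits must be in 0..3");
      buf[j] = (char)ASCII_BASE[d];
    }
    out[i] = buf;
  }
  return out;
}

// CRC images (init = 0, xor-out = 0) of the 2k single-position gen32 basis
// deltas (bits 0x2 and 0x4 of each base's nibble). Because the per-position
// gen32 delta set {0x0,0x2,0x4,0x6} is a GF(2)-linear subspace, gen32+CRC32 is
// collision-free on the full 4^k space iff these 2k images are linearly
// independent.
// [[Rcpp::export]]
NumericVector cpp_gen32_delta_basis(int k, double poly) {
  if (k < 1 || k > 16) stop("k must be in 1..16");
  uint32_t table[256];
  crc_build_table((uint32_t)poly, table);
  int size = (k + 1) / 2;
  NumericVector out(2 * k);
  uint8_t msg[8];
  for (int i = 0; i < k; ++i) {
    // nibble position of base i in the packed bytes (odd k: lone code low)
    bool high = (i % 2 == 0) && !(k % 2 == 1 && i == k - 1);
    for (int b = 0; b < 2; ++b) {
      uint8_t delta = (uint8_t)(b == 0 ? 0x2 : 0x4);
      std::memset(msg, 0, (size_t)size);
      msg[i / 2] = high ? (uint8_t)(delta << 4) : delta;
      out[2 * i + b] = (double)crc_hash(table, 0u, 0u, msg, (size_t)size);
    }
  }
  return out;
}

// [[Rcpp::export]]
int cpp_gf2_rank(NumericVector vecs) {
  std::vector<uint32_t> pivots;
  int rank = 0;
  for (R_xlen_t i = 0; i < vecs.size(); ++i) {
    uint32_t v = (uint32_t)vecs[i];
    for (size_t j = 0; j < pivots.size(); ++j) {
      uint32_t r = v ^ pivots[j];
      if (r < v) v = r;
    }
    if (v) {
      pivots.push_back(v);
      std::sort(pivots.rbegin(), pivots.rend());
      ++rank;
    }
  }
  return rank;
}

// Exact avalanche mean flip for a CRC scheme via linearity: the output XOR of
// a pair equals the init-free CRC of the input XOR-delta, so the mean over all
// single-base substitutions is a finite average over position x delta.
// [[Rcpp::export]]
double cpp_exact_mean_flip(int k, double poly, int prep) {
  if (k < 1 || k > 64) stop("k must be in 1..64");
  uint32_t table[256];
  crc_build_table((uint32_t)poly, table);
  double total = 0.0;
  long count = 0;
  if (prep == PREP_GEN32) {
    int size = (k + 1) / 2;
    std::vector<uint8_t> msg((size_t)size);
    const uint8_t deltas[3] = {0x2, 0x4, 0x6};  // pairwise XORs of nibble codes
    for (int i = 0; i < k; ++i) {
      bool high = (i % 2 == 0) && !(k % 2 == 1 && i == k - 1);
      for (int d = 0; d < 3; ++d) {
        std::fill(msg.begin(), msg.end(), 0);
        msg[i / 2] = high ? (uint8_t)(deltas[d] << 4) : deltas[d];
        uint32_t x = crc_hash(table, 0u, 0u, msg.data(), (size_t)size);
        int bits = 0;
        while (x) { x &= x - 1; ++bits; }
        total += bits / 32.0;
        ++count;
      }
    }
  } else {
    std::vector<uint8_t> msg((size_t)k);
    uint8_t deltas[6];
    int nd = 0;
    for (int a = 0; a < 4; ++a)
      for (int b = a + 1; b < 4; ++b)
        deltas[nd++] = (uint8_t)(ASCII_BASE[a] ^ ASCII_BASE[b]);
    for (int i = 0; i < k; ++i) {
      for (int d = 0; d < 6; ++d) {
        std::fill(msg.begin(), msg.end(), 0);
        msg[i] = deltas[d];
        uint32_t x = crc_hash(table, 0u, 0u, msg.data(), (size_t)k);
        int bits = 0;
        while (x) { x &= x - 1; ++bits; }
        total += bits / 32.0;
        ++count;
      }
    }
  }
  return total / count;
}

// [[Rcpp::export]]
NumericVector cpp_bucket_counts(NumericVector hashes, double m) {
  if (m < 1 || m != std::floor(m)) stop("m must be a positive integer");
  uint64_t mm = (uint64_t)m;
  NumericVector counts((R_xlen_t)mm);
  for (R_xlen_t i = 0; i < hashes.size(); ++i) {
    double h = hashes[i];
    if (ISNAN(h) || h < 0 || h != std::floor(h))
      stop("hashes must be non-negative integers");
    counts[(R_xlen_t)((uint64_t)h % mm)] += 1;
  }
  return counts;
}
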