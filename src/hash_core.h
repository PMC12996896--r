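#ifndef GENCRC32_HASH_CORE_H
#define GENCRC32_HASH_CORE_H

#include <cstdint>
#include <cstddef>
#include <cstring>

namespace gencrc32 {

// Digit order is lexicographic A<C<G<T; gen32 nibble codes are ASCII & 0x0E.
static const uint8_t ASCII_BASE[4] = {0x41, 0x43, 0x47, 0x54};  // A C G T
static const uint8_t NIBBLE_CODE[4] = {0x00, 0x02, 0x06, 0x04};

// 256-entry map ASCII -> base digit (0..3), or 0xFF for anything not ACGTacgt.
inline const uint8_t* base_digit_table() {
  static uint8_t tab[256];
  static bool ready = false;
  if (!ready) {
    std::memset(tab, 0xFF, sizeof(tab));
    tab['A'] = tab['a'] = 0;
    tab['C'] = tab['c'] = 1;
    tab['G'] = tab['g'] = 2;
    tab['T'] = tab['t'] = 3;
    ready = true;
  }
  return tab;
}

// ---- reflected CRC32, arbitrary reversed-form polynomial --------------------

inline void crc_build_table(uint32_t poly_reversed, uint32_t* table) {
  for (uint32_t i = 0; i < 256; ++i) {
    uint32_t c = i;
    for (int j = 0; j < 8; ++j)
      c = (c >> 1) ^ ((c & 1u) ? poly_reversed : 0u);
    table[i] = c;
  }
}

inline uint32_t crc_update(const uint32_t* table, uint32_t reg,
                           const uint8_t* p, size_t n) {
  for (size_t i = 0; i < n; ++i)
    reg = (reg >> 8) ^ table[(reg ^ p[i]) & 0xFFu];
  return reg;
}

inline uint32_t crc_hash(const uint32_t* table, uint32_t init, uint32_t xorout,
                         const uint8_t* p, size_t n) {
  return crc_update(table, init, p, n) ^ xorout;
}

// ---- MurmurHash3 x86_32 (Appleby, public domain) ----------------------------

inline uint32_t rotl32(uint32_t x, int8_t r) {
  return (x << r) | (x >> (32 - r));
}

inline uint32_t murmur3_32(const uint8_t* data, size_t len, uint32_t seed) {
  const uint32_t c1 = 0xcc9e2d51u, c2 = 0x1b873593u;
  uint32_t h = seed;
  const size_t nblocks = len / 4;
  for (size_t i = 0; i < nblocks; ++i) {
    uint32_t k = (uint32_t)data[4 * i]
               | ((uint32_t)data[4 * i + 1] << 8)
               | ((uint32_t)data[4 * i + 2] << 16)
               | ((uint32_t)data[4 * i + 3] << 24);
    k *= c1; k = rotl32(k, 15); k *= c2;
    h ^= k; h = rotl32(h, 13); h = h * 5u + 0xe6546b64u;
  }
  const uint8_t* tail = data + nblocks * 4;
  uint32_t k1 = 0;
  switch (len & 3) {
    case 3: k1 ^= (uint32_t)tail[2] << 16; /* fall through */
    case 2: k1 ^= (uint32_t)tail[1] << 8;  /* fall through */
    case 1: k1 ^= (uint32_t)tail[0];
            k1 *= c1; k1 = rotl32(k1, 15); k1 *= c2; h ^= k1;
  }
  h ^= (uint32_t)len;
  h ^= h >> 16; h *= 0x85ebca6bu;
  h ^= h >> 13; h *= 0xc2b2ae35u;
  h ^= h >> 16;
  return h;
}

// ---- xxHash32 (Collet, BSD) -------------------------------------------------

inline uint32_t xxh_read32(const uint8_t* p) {
  return (uint32_t)p[0] | ((uint32_t)p[1] << 8)
       | ((uint32_t)p[2] << 16) | ((uint32_t)p[3] << 24);
}

inline uint32_t xxhash32(const uint8_t* data, size_t len, uint32_t seed) {
  const uint32_t P1 = 2654435761u, P2 = 2246822519u, P3 = 3266489917u,
                 P4 = 668265263u, P5 = 374761393u;
  const uint8_t* p = data;
  const uint8_t* end = data + len;
  uint32_t h;
  if (len >= 16) {
    uint32_t v1 = seed + P1 + P2, v2 = seed + P2, v3 = seed, v4 = seed - P1;
    const uint8_t* limit = end - 16;
    do {
      v1 = rotl32(v1 + xxh_read32(p) * P2, 13) * P1; p += 4;
      v2 = rotl32(v2 + xxh_read32(p) * P2, 13) * P1; p += 4;
      v3 = rotl32(v3 + xxh_read32(p) * P2, 13) * P1; p += 4;
      v4 = rotl32(v4 + xxh_read32(p) * P2, 13) * P1; p += 4;
    } while (p <= limit);
    h = rotl32(v1, 1) + rotl32(v2, 7) + rotl32(v3, 12) + rotl32(v4, 18);
  } else {
    h = seed + P5;
  }
  h += (uint32_t)len;
  while (p + 4 <= end) {
    h = rotl32(h + xxh_read32(p) * P3, 17) * P4;
    p += 4;
  }
  while (p < end) {
    h = rotl32(h + (uint32_t)(*p) * P5, 11) * P1;
    ++p;
  }
  h ^= h >> 15; h *= P2;
  h ^= h >> 13; h *= P3;
  h ^= h >> 16;
  return h;
}

// ---- unified hashing over a configured scheme -------------------------------

enum Family { FAM_CRC32 = 0, FAM_MURMUR3 = 1, FAM_XXHASH32 = 2 };
enum Prep { PREP_NONE = 0, PREP_GEN32 = 1 };

struct HashSpec {
  int family;
  int prep;
  uint32_t table[256];
  uint32_t init, xorout, seed;
};

inline uint32_t hash_bytes(const HashSpec& s, const uint8_t* p, size_t n) {
  switch (s.family) {
    case FAM_CRC32:   return crc_hash(s.table, s.init, s.xorout, p, n);
    case FAM_MURMUR3: return murmur3_32(p, n, s.seed);
    default:          return xxhash32(p, n, s.seed);
  }
}

// gen32 packing from base digits; mirrors the shift-4-then-OR pseudocode so an
// odd k leaves the final lone code in the low nibble.
inline void pack_digits(const uint8_t* digits, int k, uint8_t* out) {
  int size = (k + 1) / 2;
  std::memset(out, 0, (size_t)size);
  for (int i = 0; i < k; ++i) {
    out[i >> 1] = (uint8_t)((out[i >> 1] << 4) | NIBBLE_CODE[digits[i]]);
  }
}

// Hash the k-mer given as base digits under the configured scheme: raw mode
// hashes uppercase ASCII, gen32 mode hashes the packed bytes.
inline uint32_t hash_digits(const HashSpec& s, const uint8_t* digits, int k,
                            uint8_t* scratch) {
  if (s.prep == PREP_GEN32) {
    pack_digits(digits, k, scratch);
    return hash_bytes(s, scratch, (size_t)((k + 1) / 2));
  }
  for (int i = 0; i < k; ++i) scratch[i] = ASCII_BASE[digits[i]];
  return hash_bytes(s, scratch, (size_t)k);
}

// Decode index -> digits, most-significant base first (lexicographic A<C<G<T).
inline void index_to_digits(uint64_t idx, int k, uint8_t* digits) {
  for (int j = k - 1; j >= 0; --j) {
    digits[j] = (uint8_t)(idx & 3u);
    idx >>= 2;
  }
}

}  // namespace gencrc32

#endif
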