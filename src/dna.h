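#pragma once

// 2-bit DNA alphabet: A=0, C=1, G=2, T=3, so that complement(x) = x XOR 3.
// k-mers (k <= 63) are packed into an unsigned 128-bit word, first base in
// the highest occupied bit pair; m-mers (m <= 32) into a uint64.

#include <cstdint>
#include <string>
#include <stdexcept>
#include "succinct.h"

namespace kdx {

typedef unsigned __int128 kmer_t;

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}
inline char code_base(int c) { return "ACGT"[c & 3]; }

// seeded 64-bit mixer (splitmix64 finalizer), the hash h defining the
// random minimizer order and all MPHF placements
inline uint64_t mix64(uint64_t x, uint64_t seed) {
  x += seed + 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

inline kmer_t pack_kmer(const char* s, uint32_t k) {
  kmer_t g = 0;
  for (uint32_t i = 0; i < k; ++i) {
    int c = base_code(s[i]);
    if (c < 0) throw std::invalid_argument(std::string("invalid base '") + s[i] +
                                           "' at position " + std::to_string(i + 1));
    g = (g << 2) | kmer_t(c);
  }
  return g;
}
inline std::string unpack_kmer(kmer_t g, uint32_t k) {
  std::string s(k, 'A');
  for (uint32_t i = 0; i < k; ++i) {
    s[k - 1 - i] = code_base(int(g & 3));
    g >>= 2;
  }
  return s;
}
inline kmer_t revcomp_kmer(kmer_t g, uint32_t k) {
  kmer_t r = 0;
  for (uint32_t i = 0; i < k; ++i) {
    r = (r << 2) | ((g & 3) ^ 3);
    g >>= 2;
  }
  return r;
}
inline uint64_t revcomp_mmer(uint64_t g, uint32_t m) {
  uint64_t r = 0;
  for (uint32_t i = 0; i < m; ++i) {
    r = (r << 2) | ((g & 3) ^ 3);
    g >>= 2;
  }
  return r;
}

// canonical 64-bit key of a packed k-mer: min over strands for k <= 32,
// a mixed fingerprint of that minimum for larger k (collisions only add
// candidates that the verifying scan rejects)
inline uint64_t canonical_key(kmer_t g, uint32_t k, uint64_t seed) {
  kmer_t rc = revcomp_kmer(g, k);
  kmer_t c = g < rc ? g : rc;
  if (k <= 32) return uint64_t(c);
  return mix64(uint64_t(c), seed ^ 0x5bd1e995u) ^ mix64(uint64_t(c >> 64), seed + 0x27d4eb2fu);
}

// 2-bit packed concatenation of the cover strings plus their endpoints
struct PackedStrings {
  CompactVector bits;               // width 2, N entries
  std::vector<uint64_t> endpoints;  // E[0..p], E[0]=0, E[p]=N
  uint64_t N = 0;

  uint64_t p() const { return endpoints.empty() ? 0 : endpoints.size() - 1; }
  int base_at(uint64_t t) const { return int(bits.get(t)); }
  kmer_t kmer_at(uint64_t t, uint32_t k) const {
    kmer_t g = 0;
    for (uint32_t i = 0; i < k; ++i) g = (g << 2) | kmer_t(bits.get(t + i));
    return g;
  }
  // index j of the string containing position t (E[j] <= t < E[j+1])
  uint64_t string_of(uint64_t t) const {
    size_t lo = 0, hi = p();
    while (hi - lo > 1) {
      size_t mid = (lo + hi) / 2;
      if (endpoints[mid] <= t) lo = mid; else hi = mid;
    }
    return lo;
  }
  bool valid_window(uint64_t t, uint32_t k) const {
    if (t + k > N) return false;
    uint64_t j = string_of(t);
    return t + k <= endpoints[j + 1];
  }
  void save(std::ostream& os) const {
    write_u64(os, N);
    bits.save(os);
    write_vec(os, endpoints);
  }
  void load(std::istream& is) {
    N = read_u64(is);
    bits.load(is);
    endpoints = read_vec(is);
  }
};

inline PackedStrings pack_strings(const std::vector<std::string>& strs) {
  PackedStrings ps;
  uint64_t N = 0;
  for (const auto& s : strs) N += s.size();
  ps.N = N;
  ps.bits.init(N, 2);
  ps.endpoints.clear();
  ps.endpoints.push_back(0);
  uint64_t t = 0;
  for (const auto& s : strs) {
    for (size_t i = 0; i < s.size(); ++i) {
      int c = base_code(s[i]);
      if (c < 0)
        throw std::invalid_argument("invalid base '" + std::string(1, s[i]) +
                                    "' at position " + std::to_string(i + 1) +
                                    " of string " + std::to_string(&s - strs.data() + 1));
      ps.bits.set(t++, uint64_t(c));
    }
    ps.endpoints.push_back(t);
  }
  return ps;
}

}  // namespace kdx
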