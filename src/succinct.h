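#pragma once

// Plain-word succinct building blocks: bit vector with rank samples,
// fixed-width compact vector, Elias-Fano monotone sequence.
// All serialization is little-endian uint64 words (x86 layout written as-is).

#include <cstdint>
#include <cstring>
#include <vector>
#include <string>
#include <stdexcept>
#include <iostream>

namespace kdx {

inline void write_u64(std::ostream& os, uint64_t x) {
  os.write(reinterpret_cast<const char*>(&x), sizeof(x));
}
inline uint64_t read_u64(std::istream& is) {
  uint64_t x = 0;
  is.read(reinterpret_cast<char*>(&x), sizeof(x));
  if (!is) throw std::runtime_error("index file truncated");
  return x;
}
inline void write_vec(std::ostream& os, const std::vector<uint64_t>& v) {
  write_u64(os, v.size());
  if (!v.empty())
    os.write(reinterpret_cast<const char*>(v.data()), v.size() * sizeof(uint64_t));
}
inline std::vector<uint64_t> read_vec(std::istream& is) {
  uint64_t sz = read_u64(is);
  std::vector<uint64_t> v(sz);
  if (sz) {
    is.read(reinterpret_cast<char*>(v.data()), sz * sizeof(uint64_t));
    if (!is) throw std::runtime_error("index file truncated");
  }
  return v;
}

inline uint32_t ceil_log2(uint64_t x) {
  // smallest e with 2^e >= x; ceil_log2(0) = 0, ceil_log2(1) = 0
  uint32_t e = 0;
  while ((uint64_t(1) << e) < x) {
    ++e;
    if (e == 64) break;
  }
  return e;
}
inline uint32_t floor_log2(uint64_t x) {
  // largest e with 2^e <= x (x >= 1)
  return 63u - uint32_t(__builtin_clzll(x));
}

struct BitVector {
  std::vector<uint64_t> words;
  uint64_t nbits = 0;

  void resize_bits(uint64_t n) {
    nbits = n;
    words.assign((n + 63) / 64, 0);
  }
  void set(uint64_t i) { words[i >> 6] |= (uint64_t(1) << (i & 63)); }
  bool get(uint64_t i) const {
    return (words[i >> 6] >> (i & 63)) & 1;
  }
  uint64_t count_ones() const {
    uint64_t c = 0;
    for (uint64_t w : words) c += __builtin_popcountll(w);
    return c;
  }
  void save(std::ostream& os) const {
    write_u64(os, nbits);
    write_vec(os, words);
  }
  void load(std::istream& is) {
    nbits = read_u64(is);
    words = read_vec(is);
  }
};

// Rank-supported bit vector: one cumulative popcount sample per 16 words
// (1024 bits), keeping the o(n) overhead small even for tiny levels.
struct RankBV {
  BitVector bv;
  std::vector<uint64_t> samples;  // ones before word block i*16

  void build_rank() {
    samples.assign(bv.words.empty() ? 0 : (bv.words.size() + 15) / 16, 0);
    uint64_t acc = 0;
    for (size_t w = 0; w < bv.words.size(); ++w) {
      if (w % 16 == 0) samples[w / 16] = acc;
      acc += __builtin_popcountll(bv.words[w]);
    }
    total_ones_ = acc;
  }
  // ones in [0, pos)
  uint64_t rank1(uint64_t pos) const {
    uint64_t w = pos >> 6;
    uint64_t r = samples[w >> 4];
    for (uint64_t i = (w >> 4) << 4; i < w; ++i)
      r += __builtin_popcountll(bv.words[i]);
    uint64_t rem = pos & 63;
    if (rem) r += __builtin_popcountll(bv.words[w] & ((uint64_t(1) << rem) - 1));
    return r;
  }
  uint64_t total_ones() const { return total_ones_; }
  uint64_t bits() const { return bv.nbits + samples.size() * 64; }
  void save(std::ostream& os) const {
    bv.save(os);
    write_vec(os, samples);
    write_u64(os, total_ones_);
  }
  void load(std::istream& is) {
    bv.load(is);
    samples = read_vec(is);
    total_ones_ = read_u64(is);
  }
 private:
  uint64_t total_ones_ = 0;
};

struct CompactVector {
  uint32_t width = 0;   // bits per entry, 0..64 (0 => all entries are 0)
  uint64_t n = 0;
  std::vector<uint64_t> words;

  void init(uint64_t n_, uint32_t width_) {
    n = n_;
    width = width_;
    words.assign(width ? (n * width + 63) / 64 : 0, 0);
  }
  void set(uint64_t i, uint64_t v) {
    if (!width) return;
    uint64_t b = i * width, w = b >> 6, off = b & 63;
    words[w] |= v << off;
    if (off + width > 64) words[w + 1] |= v >> (64 - off);
  }
  uint64_t get(uint64_t i) const {
    if (!width) return 0;
    uint64_t b = i * width, w = b >> 6, off = b & 63;
    uint64_t v = words[w] >> off;
    if (off + width > 64) v |= words[w + 1] << (64 - off);
    return width == 64 ? v : (v & ((uint64_t(1) << width) - 1));
  }
  uint64_t bits() const { return n * uint64_t(width); }
  void save(std::ostream& os) const {
    write_u64(os, width);
    write_u64(os, n);
    write_vec(os, words);
  }
  void load(std::istream& is) {
    width = uint32_t(read_u64(is));
    n = read_u64(is);
    words = read_vec(is);
  }
};

// Elias-Fano encoding of a non-decreasing sequence S[0..n) with S[n-1] <= U.
// Payload is n*low_width + (n + (U >> low_width)) bits, within the classic
// n*ceil(log2(U/n)) + 2n bound. Select on the high bits is a per-word
// cumulative-popcount binary search (o(n) extra, accounted separately).
struct EliasFano {
  uint64_t n = 0, universe = 0;
  uint32_t low_width = 0;
  CompactVector low;
  BitVector high;
  std::vector<uint64_t> high_cum;  // ones before each word of `high`

  void build(const std::vector<uint64_t>& vals, uint64_t U) {
    n = vals.size();
    universe = U;
    for (size_t i = 0; i < vals.size(); ++i) {
      if (i && vals[i] < vals[i - 1])
        throw std::invalid_argument("sequence is not non-decreasing");
      if (vals[i] > U) throw std::invalid_argument("value exceeds declared universe");
    }
    low_width = (n && U > n) ? floor_log2(U / n) : 0;
    low.init(n, low_width);
    high.resize_bits(n ? n + (U >> low_width) : 0);
    for (uint64_t i = 0; i < n; ++i) {
      uint64_t v = vals[i];
      if (low_width) low.set(i, v & ((uint64_t(1) << low_width) - 1));
      high.set((v >> low_width) + i);
    }
    build_cum();
  }
  void build_cum() {
    high_cum.assign(high.words.size() + 1, 0);
    for (size_t w = 0; w < high.words.size(); ++w)
      high_cum[w + 1] = high_cum[w] + __builtin_popcountll(high.words[w]);
  }
  // position of the i-th (0-based) one in `high`
  uint64_t select1(uint64_t i) const {
    size_t lo = 0, hi = high.words.size();
    while (hi - lo > 1) {  // largest word w with high_cum[w] <= i
      size_t mid = (lo + hi) / 2;
      if (high_cum[mid] <= i) lo = mid; else hi = mid;
    }
    uint64_t rem = i - high_cum[lo];
    uint64_t w = high.words[lo];
    while (rem--) w &= w - 1;
    return lo * 64 + __builtin_ctzll(w);
  }
  uint64_t access(uint64_t i) const {
    if (i >= n) throw std::out_of_range("Elias-Fano index out of range");
    uint64_t h = select1(i) - i;
    return (h << low_width) | low.get(i);
  }
  // smallest i with S[i] >= x (or n if none)
  uint64_t successor_rank(uint64_t x) const {
    uint64_t lo = 0, hi = n;
    while (lo < hi) {
      uint64_t mid = (lo + hi) / 2;
      if (access(mid) >= x) hi = mid; else lo = mid + 1;
    }
    return lo;
  }
  uint64_t payload_bits() const { return low.bits() + high.nbits; }
  uint64_t bound_bits() const {
    // n*ceil(log2(U/n)) + 2n with the U<=n guard
    if (!n) return 0;
    uint64_t q = (universe + n - 1) / n;  // ceil(U/n)
    return n * uint64_t(ceil_log2(q)) + 2 * n;
  }
  void save(std::ostream& os) const {
    write_u64(os, n);
    write_u64(os, universe);
    write_u64(os, low_width);
    low.save(os);
    high.save(os);
  }
  void load(std::istream& is) {
    n = read_u64(is);
    universe = read_u64(is);
    low_width = uint32_t(read_u64(is));
    low.load(is);
    high.load(is);
    build_cum();
  }
};

}  // namespace kdx
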