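#pragma once

// Minimizer-bucketed exact k-mer dictionary over a de Bruijn graph path
// cover: 2-bit packed strings + Elias-Fano endpoints, an MPHF over the
// distinct minimizers with Elias-Fano prefix-summed bucket sizes and a
// fixed-width array of absolute super-k-mer offsets, plus a skew index
// (per-size-class MPHFs) that bounds lookup work on heavy buckets.

#include <algorithm>
#include <cstdint>
#include <fstream>
#include <random>
#include <unordered_set>
#include <vector>
#include "succinct.h"
#include "dna.h"
#include "mphf.h"

namespace kdx {

struct DictConfig {
  uint32_t k = 31, m = 20;
  bool canonical = false;
  uint32_t l = 6, L = 12;
  uint64_t seed = 1;
};

struct SuperKmer {
  uint64_t offset;       // absolute position in [0, N) of the first base
  uint32_t len;          // K bases, k <= K <= 2k - m
  uint64_t minimizer;    // packed m-mer shared by all its k-mers
  uint64_t string_index;
};

struct Counters {
  uint64_t f_evals = 0, skew_evals = 0, superkmers_scanned = 0,
           kmer_cmps = 0, ext_attempts = 0, extensions = 0, bucket_scans = 0;
};

struct LookupRes {
  int64_t id = -1;
  int orient = 0;  // 1 forward, -1 reverse complement, 0 none
  uint64_t begin = 0, end = 0, t = 0, w = 0, j = 0;
};

// ---------------------------------------------------------------- minimizers

struct MmerArrays {
  // per m-mer start position within one string/pattern
  std::vector<uint64_t> fpack, fhash, rpack, rhash;
};

inline void fill_mmer_arrays(const int* codes, uint64_t len, uint32_t m,
                             uint64_t seed, bool canonical, MmerArrays& a) {
  uint64_t npos = len >= m ? len - m + 1 : 0;
  a.fpack.assign(npos, 0);
  a.fhash.assign(npos, 0);
  if (canonical) {
    a.rpack.assign(npos, 0);
    a.rhash.assign(npos, 0);
  }
  if (!npos) return;
  uint64_t mask = m == 32 ? ~uint64_t(0) : (uint64_t(1) << (2 * m)) - 1;
  uint64_t f = 0, r = 0;
  for (uint64_t i = 0; i < len; ++i) {
    int c = codes[i] < 0 ? 0 : codes[i];  // invalid positions never consulted
    f = ((f << 2) | uint64_t(c)) & mask;
    r = (r >> 2) | (uint64_t(c ^ 3) << (2 * (m - 1)));
    if (i + 1 >= m) {
      uint64_t t = i + 1 - m;
      a.fpack[t] = f;
      a.fhash[t] = mix64(f, seed);
      if (canonical) {
        a.rpack[t] = r;
        a.rhash[t] = mix64(r, seed);
      }
    }
  }
}

struct WinMin {
  uint64_t mmer = 0;  // packed minimizer (in its winning orientation)
  uint64_t pos = 0;   // start position of the m-mer within the window's string
  bool rc = false;    // true when the reverse-strand m-mer won (canonical)
};

// minimizer of the k-mer window starting at position w: regular = leftmost
// hash-argmin over the k-m+1 forward m-mers; canonical = the smaller (under
// (hash, packed value)) of the forward minimizer and the reverse-strand
// minimizer, whose own leftmost tie-break is rightmost in forward coordinates
inline WinMin window_minimizer(const MmerArrays& a, uint64_t w, uint32_t k,
                               uint32_t m, bool canonical) {
  uint64_t span = k - m + 1;
  uint64_t fbest = w;
  for (uint64_t t = w + 1; t < w + span; ++t)
    if (a.fhash[t] < a.fhash[fbest]) fbest = t;
  WinMin res;
  if (!canonical) {
    res.mmer = a.fpack[fbest];
    res.pos = fbest;
    return res;
  }
  uint64_t rbest = w;
  for (uint64_t t = w + 1; t < w + span; ++t)
    if (a.rhash[t] <= a.rhash[rbest]) rbest = t;
  bool forward = a.fhash[fbest] < a.rhash[rbest] ||
                 (a.fhash[fbest] == a.rhash[rbest] && a.fpack[fbest] <= a.rpack[rbest]);
  if (forward) {
    res.mmer = a.fpack[fbest];
    res.pos = fbest;
  } else {
    res.mmer = a.rpack[rbest];
    res.pos = rbest;
    res.rc = true;
  }
  return res;
}

// minimizer of a single packed k-mer
inline WinMin kmer_minimizer(kmer_t g, uint32_t k, uint32_t m, uint64_t seed,
                             bool canonical, MmerArrays& scratch) {
  std::vector<int> codes(k);
  for (uint32_t i = 0; i < k; ++i)
    codes[i] = int((g >> (2 * (k - 1 - i))) & 3);
  fill_mmer_arrays(codes.data(), k, m, seed, canonical, scratch);
  return window_minimizer(scratch, 0, k, m, canonical);
}

// left-to-right partition of each string's k-mers into runs with constant
// minimizer, each run capped at k-m+1 k-mers
inline std::vector<SuperKmer> parse_super_kmers(const PackedStrings& ps,
                                                uint32_t k, uint32_t m,
                                                uint64_t seed, bool canonical) {
  std::vector<SuperKmer> out;
  MmerArrays a;
  std::vector<int> codes;
  uint64_t p = ps.p();
  for (uint64_t j = 0; j < p; ++j) {
    uint64_t beg = ps.endpoints[j], end = ps.endpoints[j + 1], len = end - beg;
    codes.resize(len);
    for (uint64_t i = 0; i < len; ++i) codes[i] = ps.base_at(beg + i);
    fill_mmer_arrays(codes.data(), len, m, seed, canonical, a);
    uint64_t nwin = len - k + 1;
    uint64_t run_start = 0, run_kmers = 0;
    uint64_t cur_min = 0;
    for (uint64_t w = 0; w < nwin; ++w) {
      WinMin wm = window_minimizer(a, w, k, m, canonical);
      if (run_kmers == 0 || wm.mmer != cur_min || run_kmers == k - m + 1) {
        if (run_kmers > 0)
          out.push_back({beg + run_start, uint32_t(w - run_start + k - 1),
                         cur_min, j});
        run_start = w;
        run_kmers = 0;
        cur_min = wm.mmer;
      }
      ++run_kmers;
    }
    out.push_back({beg + run_start, uint32_t(nwin - run_start + k - 1), cur_min, j});
  }
  return out;
}

// ---------------------------------------------------------------- dictionary

struct SkewPartition {
  uint64_t nkeys = 0;
  uint32_t width = 0;
  Mphf f;
  CompactVector V;
};

// "small" iff ceil(log2(s)) <= l, else the unique i with 2^i < s <= 2^(i+1),
// clamped to L; returns -1 for small
inline int skew_partition_of(uint64_t s, uint32_t l, uint32_t L) {
  if (ceil_log2(s) <= l) return -1;
  uint32_t i = ceil_log2(s) - 1;
  return int(i > L ? L : i);
}

struct Dictionary {
  DictConfig cfg;
  PackedStrings ps;
  EliasFano endpoints_ef;  // E[0..p], universe N
  Mphf fmin;               // over the M distinct minimizers
  EliasFano sizes;         // M+1 prefix-summed bucket sizes, universe z
  CompactVector offsets;   // z absolute offsets, width ceil(log2 N)
  std::vector<SkewPartition> parts;  // L-l+1 partitions (possibly empty stubs)
  bool skew_enabled = true;
  uint64_t n = 0, z = 0, M = 0, max_bucket = 0;

  uint64_t N() const { return ps.N; }
  uint64_t p() const { return ps.p(); }
  uint64_t kmers_before_string(uint64_t j) const {
    return ps.endpoints[j] - j * (cfg.k - 1);
  }

  WinMin minimizer_of(kmer_t g) const {
    MmerArrays scratch;
    return kmer_minimizer(g, cfg.k, cfg.m, cfg.seed, cfg.canonical, scratch);
  }

  struct BucketInfo {
    uint64_t b = 0, begin = 0, end = 0;
    bool known = false;
  };

  BucketInfo locate_bucket(uint64_t r, Counters* c) const {
    BucketInfo bi;
    bi.b = fmin.eval(r);
    if (c) ++c->f_evals;
    bi.begin = sizes.access(bi.b);
    bi.end = sizes.access(bi.b + 1);
    // foreign-minimizer guard: the MPHF locates *a* bucket for any m-mer;
    // compare r with the minimizer of the first k-mer of the bucket
    uint64_t t0 = offsets.get(bi.begin);
    bi.known = minimizer_of(ps.kmer_at(t0, cfg.k)).mmer == r;
    return bi;
  }

  // scan the super-k-mer whose offset is t, comparing against g (forward)
  // and, when cmp_rc, against grc (reverse complement match)
  bool scan_super_kmer(uint64_t t, kmer_t g, kmer_t grc, bool cmp_rc,
                       LookupRes& res, Counters* c) const {
    uint32_t k = cfg.k;
    uint64_t j = ps.string_of(t);
    uint64_t send = ps.endpoints[j + 1];
    uint64_t wmax = std::min<uint64_t>(k - cfg.m + 1, send - t - k + 1);
    if (c) ++c->superkmers_scanned;
    kmer_t mask = (kmer_t(1) << (2 * k)) - 1;
    kmer_t cand = ps.kmer_at(t, k);
    for (uint64_t w = 0; w < wmax; ++w) {
      if (w) cand = ((cand << 2) | kmer_t(ps.base_at(t + k - 1 + w))) & mask;
      if (c) ++c->kmer_cmps;
      int orient = 0;
      if (cand == g) orient = 1;
      else if (cmp_rc && cand == grc) orient = -1;
      if (orient) {
        res.t = t;
        res.w = w;
        res.j = j;
        res.orient = orient;
        res.id = int64_t(t + w - j * (k - 1));
        return true;
      }
    }
    return false;
  }

  // search one bucket for g (and grc when cmp_rc); skew index used on heavy
  // buckets to scan a single candidate super-k-mer
  bool search_bucket(const BucketInfo& bi, kmer_t g, kmer_t grc, bool cmp_rc,
                     LookupRes& res, Counters* c) const {
    res.begin = bi.begin;
    res.end = bi.end;
    if (c) ++c->bucket_scans;
    uint64_t s = bi.end - bi.begin;
    int pi = skew_partition_of(s, cfg.l, cfg.L);
    if (skew_enabled && pi >= 0) {
      const SkewPartition& part = parts[pi - int(cfg.l)];
      if (part.nkeys == 0) return false;
      uint64_t key = canonical_key(g, cfg.k, cfg.seed);
      uint64_t q = part.V.get(part.f.eval(key));
      if (c) ++c->skew_evals;
      if (q >= s) return false;  // definitive absence
      return scan_super_kmer(offsets.get(bi.begin + q), g, grc, cmp_rc, res, c);
    }
    for (uint64_t q = 0; q < s; ++q)
      if (scan_super_kmer(offsets.get(bi.begin + q), g, grc, cmp_rc, res, c))
        return true;
    return false;
  }

  LookupRes lookup_packed(kmer_t g, Counters* c = nullptr) const {
    LookupRes res;
    kmer_t grc = revcomp_kmer(g, cfg.k);
    if (cfg.canonical) {
      BucketInfo bi = locate_bucket(minimizer_of(g).mmer, c);
      if (bi.known) search_bucket(bi, g, grc, true, res, c);
      else { res.begin = bi.begin; res.end = bi.end; }
      return res;
    }
    // regular modality: search g first, then its reverse complement
    BucketInfo bi = locate_bucket(minimizer_of(g).mmer, c);
    if (bi.known && search_bucket(bi, g, grc, false, res, c)) return res;
    BucketInfo bi2 = locate_bucket(minimizer_of(grc).mmer, c);
    if (bi2.known && search_bucket(bi2, grc, g, false, res, c)) {
      res.orient = -1;
      return res;
    }
    res.id = -1;
    res.orient = 0;
    res.begin = bi2.begin;
    res.end = bi2.end;
    return res;
  }

  std::string access(uint64_t i) const {
    if (i >= n) throw std::out_of_range("identifier out of [0, n)");
    // largest j with E[j] - j(k-1) <= i, then t = i + j(k-1)
    uint64_t lo = 0, hi = p();
    while (hi - lo > 1) {
      uint64_t mid = (lo + hi) / 2;
      if (kmers_before_string(mid) <= i) lo = mid; else hi = mid;
    }
    uint64_t t = i + lo * (cfg.k - 1);
    return unpack_kmer(ps.kmer_at(t, cfg.k), cfg.k);
  }
};

// ------------------------------------------------------------------- build

inline Dictionary build_dictionary(const std::vector<std::string>& strings,
                                   DictConfig cfg, bool use_skew, bool verify) {
  if (cfg.m < 1 || cfg.m > cfg.k || cfg.m > 32)
    throw std::invalid_argument("need 1 <= m <= min(k, 32)");
  if (cfg.k > 63) throw std::invalid_argument("k > 63 not supported");
  if (cfg.l >= cfg.L) throw std::invalid_argument("need 0 <= l < L");
  if (strings.empty()) throw std::invalid_argument("empty input collection");
  for (size_t j = 0; j < strings.size(); ++j)
    if (strings[j].size() < cfg.k)
      throw std::invalid_argument("string " + std::to_string(j + 1) +
                                  " is shorter than k");
  Dictionary d;
  d.cfg = cfg;
  d.skew_enabled = use_skew;
  d.ps = pack_strings(strings);
  d.endpoints_ef.build(d.ps.endpoints, d.ps.N);
  d.n = d.ps.N - d.ps.p() * (cfg.k - 1);

  if (verify) {
    std::unordered_set<uint64_t> seen;
    seen.reserve(d.n * 2);
    std::vector<kmer_t> wide;  // collision fallback for k > 32 fingerprints
    for (uint64_t t = 0; t + cfg.k <= d.ps.N; ++t) {
      if (!d.ps.valid_window(t, cfg.k)) continue;
      kmer_t g = d.ps.kmer_at(t, cfg.k);
      kmer_t rc = revcomp_kmer(g, cfg.k);
      kmer_t canon = g < rc ? g : rc;
      if (cfg.k <= 32) {
        if (!seen.insert(uint64_t(canon)).second)
          throw std::runtime_error("duplicate k-mer at offset " + std::to_string(t));
      } else {
        wide.push_back(canon);
      }
    }
    if (!wide.empty()) {
      std::sort(wide.begin(), wide.end());
      if (std::adjacent_find(wide.begin(), wide.end()) != wide.end())
        throw std::runtime_error("duplicate k-mer in input");
    }
  }

  std::vector<SuperKmer> sks =
      parse_super_kmers(d.ps, cfg.k, cfg.m, cfg.seed, cfg.canonical);
  d.z = sks.size();

  std::vector<uint64_t> mins;
  mins.reserve(sks.size());
  for (const auto& sk : sks) mins.push_back(sk.minimizer);
  std::sort(mins.begin(), mins.end());
  mins.erase(std::unique(mins.begin(), mins.end()), mins.end());
  d.M = mins.size();
  d.fmin.build(mins, mix64(cfg.seed, 0x6d696e)); // salt: minimizer MPHF

  std::vector<uint64_t> bucket_of(sks.size());
  std::vector<uint64_t> counts(d.M, 0);
  for (size_t i = 0; i < sks.size(); ++i) {
    bucket_of[i] = d.fmin.eval(sks[i].minimizer);
    ++counts[bucket_of[i]];
  }
  d.max_bucket = *std::max_element(counts.begin(), counts.end());

  std::vector<uint64_t> psum(d.M + 1, 0);
  for (uint64_t b = 0; b < d.M; ++b) psum[b + 1] = psum[b] + counts[b];
  d.sizes.build(psum, d.z);

  std::vector<uint32_t> order(sks.size());
  for (uint32_t i = 0; i < order.size(); ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](uint32_t a, uint32_t b) {
    if (bucket_of[a] != bucket_of[b]) return bucket_of[a] < bucket_of[b];
    return sks[a].offset < sks[b].offset;
  });
  d.offsets.init(d.z, std::max<uint32_t>(1, ceil_log2(d.ps.N)));
  for (uint64_t i = 0; i < d.z; ++i) d.offsets.set(i, sks[order[i]].offset);

  // skew index over heavy buckets
  d.parts.assign(cfg.L - cfg.l + 1, SkewPartition());
  if (use_skew && d.max_bucket > (uint64_t(1) << cfg.l)) {
    uint32_t np = cfg.L - cfg.l + 1;
    std::vector<std::vector<uint64_t>> keys(np), vals(np);
    for (uint64_t b = 0, pos = 0; b < d.M; pos += counts[b], ++b) {
      uint64_t s = counts[b];
      int pi = skew_partition_of(s, cfg.l, cfg.L);
      if (pi < 0) continue;
      uint32_t slot = uint32_t(pi) - cfg.l;
      for (uint64_t q = 0; q < s; ++q) {
        const SuperKmer& sk = sks[order[pos + q]];
        kmer_t mask = (kmer_t(1) << (2 * cfg.k)) - 1;
        kmer_t g = d.ps.kmer_at(sk.offset, cfg.k);
        for (uint64_t w = 0;; ++w) {
          if (w) g = ((g << 2) | kmer_t(d.ps.base_at(sk.offset + cfg.k - 1 + w))) & mask;
          keys[slot].push_back(canonical_key(g, cfg.k, cfg.seed));
          vals[slot].push_back(q);
          if (w + cfg.k == sk.len) break;
        }
      }
    }
    int top = -1;
    for (int i = int(np) - 1; i >= 0; --i)
      if (!keys[i].empty()) { top = i; break; }
    for (uint32_t slot = 0; slot < np; ++slot) {
      if (keys[slot].empty()) continue;
      SkewPartition& part = d.parts[slot];
      part.nkeys = keys[slot].size();
      uint32_t i = cfg.l + slot;
      part.width = i + 1;
      if (int(slot) == top)
        part.width = std::max<uint32_t>(part.width, ceil_log2(d.max_bucket));
      part.f.build(keys[slot], mix64(cfg.seed, 0x736b00 + i)); // salt: skew part i
      part.V.init(part.nkeys, part.width);
      for (uint64_t t = 0; t < part.nkeys; ++t)
        part.V.set(part.f.eval(keys[slot][t]), vals[slot][t]);
    }
  }
  return d;
}

// --------------------------------------------------------------- streaming

struct StreamOut {
  std::vector<int64_t> id;
  std::vector<int> orient;
  Counters counters;
};

inline void stream_pattern(const Dictionary& d, const std::string& pattern,
                           bool orientation_cache, StreamOut& out) {
  uint32_t k = d.cfg.k, m = d.cfg.m;
  uint64_t len = pattern.size();
  if (len < k) return;
  std::vector<int> codes(len);
  for (uint64_t i = 0; i < len; ++i) codes[i] = base_code(pattern[i]);
  MmerArrays a;
  fill_mmer_arrays(codes.data(), len, m, d.cfg.seed, true, a);  // both strands
  // note: regular modality needs reverse-strand arrays too (for the rc-search
  // stage), canonical uses both by definition; fill both unconditionally
  Counters& c = out.counters;

  kmer_t mask = (kmer_t(1) << (2 * k)) - 1;
  kmer_t g = 0, grc = 0;
  int64_t last_invalid = -1;

  // cached state: minimizer + bucket per search stage (canonical has one
  // stage; regular has a forward and a reverse-complement stage)
  struct StageCache {
    bool have_r = false, bucket_valid = false;
    uint64_t r = 0;
    Dictionary::BucketInfo bi;
  } stA, stB;
  int64_t jlast = -1;
  int orient = 1;

  auto wmin_fwd = [&](uint64_t w) {  // minimizer of the window under modality
    return window_minimizer(a, w, k, m, d.cfg.canonical).mmer;
  };
  auto wmin_rc = [&](uint64_t w) {
    // regular minimizer of revcomp(window): min reverse-strand hash,
    // leftmost in that strand's direction = rightmost forward position
    uint64_t best = w;
    for (uint64_t t = w + 1; t <= w + k - m; ++t)
      if (a.rhash[t] <= a.rhash[best]) best = t;
    return a.rpack[best];
  };

  for (uint64_t i = 0; i < len; ++i) {
    int cd = codes[i];
    if (cd < 0) last_invalid = int64_t(i);
    g = ((g << 2) | kmer_t(cd < 0 ? 0 : cd)) & mask;
    grc = (grc >> 2) | (kmer_t((cd < 0 ? 0 : cd) ^ 3) << (2 * (k - 1)));
    if (i + 1 < k) continue;
    uint64_t w = i + 1 - k;
    if (int64_t(w) <= last_invalid) {  // invalid base inside the window
      out.id.push_back(-1);
      out.orient.push_back(0);
      stA = StageCache();
      stB = StageCache();
      jlast = -1;
      continue;
    }
    LookupRes res;
    bool hit = false;

    // extension attempt from the last confirmed match
    if (jlast >= 0) {
      ++c.ext_attempts;
      bool back = orientation_cache && orient == -1;
      if (!back) {
        uint64_t t = uint64_t(jlast) + 1;
        if (t + k <= d.ps.N && d.ps.valid_window(t, k) && d.ps.kmer_at(t, k) == g) {
          uint64_t j = d.ps.string_of(t);
          res.t = t; res.w = 0; res.j = j;
          res.id = int64_t(t - j * (k - 1));
          res.orient = 1;
          hit = true;
        }
      } else if (jlast >= 1) {
        uint64_t t = uint64_t(jlast) - 1;
        if (d.ps.valid_window(t, k) && d.ps.kmer_at(t, k) == grc) {
          uint64_t j = d.ps.string_of(t);
          res.t = t; res.w = 0; res.j = j;
          res.id = int64_t(t - j * (k - 1));
          res.orient = -1;
          hit = true;
        }
      }
      if (hit) ++c.extensions;
    }

    if (!hit) {
      // stage A: bucket of the (modality) minimizer of g
      uint64_t rA = wmin_fwd(w);
      bool skip = false;
      if (stA.have_r && rA == stA.r && stA.bucket_valid) {
        if (!stA.bi.known) skip = true;  // minimizer not in M: definitive miss
      } else {
        stA.bi = d.locate_bucket(rA, &c);
        stA.bucket_valid = true;
      }
      stA.have_r = true;
      stA.r = rA;
      if (!skip && stA.bi.known)
        hit = d.search_bucket(stA.bi, g, grc, d.cfg.canonical, res, &c);
      if (!hit && !d.cfg.canonical) {
        // stage B: reverse-complement search
        uint64_t rB = wmin_rc(w);
        bool skipB = false;
        if (stB.have_r && rB == stB.r && stB.bucket_valid) {
          if (!stB.bi.known) skipB = true;
        } else {
          stB.bi = d.locate_bucket(rB, &c);
          stB.bucket_valid = true;
        }
        stB.have_r = true;
        stB.r = rB;
        if (!skipB && stB.bi.known &&
            d.search_bucket(stB.bi, grc, g, false, res, &c)) {
          res.orient = -1;
          hit = true;
        }
      }
    }

    if (hit) {
      out.id.push_back(res.id);
      out.orient.push_back(res.orient);
      jlast = int64_t(res.t + res.w);
      if (res.orient != 0) orient = res.orient;
    } else {
      out.id.push_back(-1);
      out.orient.push_back(0);
      jlast = -1;  // minimizer/bucket caches kept
    }
  }
}

// ------------------------------------------------------------ serialization

const uint32_t kIndexVersion = 1;

inline void save_dictionary(const Dictionary& d, const std::string& path) {
  std::ofstream os(path, std::ios::binary);
  if (!os) throw std::runtime_error("cannot open '" + path + "' for writing");
  os.write("SSHX", 4);
  write_u64(os, kIndexVersion);
  write_u64(os, d.cfg.k);
  write_u64(os, d.cfg.m);
  write_u64(os, d.cfg.canonical ? 1 : 0);
  write_u64(os, d.cfg.l);
  write_u64(os, d.cfg.L);
  write_u64(os, d.cfg.seed);
  write_u64(os, d.skew_enabled ? 1 : 0);
  write_u64(os, d.n);
  write_u64(os, d.z);
  write_u64(os, d.M);
  write_u64(os, d.max_bucket);
  write_u64(os, d.ps.N);
  d.ps.bits.save(os);
  d.endpoints_ef.save(os);
  d.fmin.save(os);
  d.sizes.save(os);
  d.offsets.save(os);
  write_u64(os, d.parts.size());
  for (const auto& part : d.parts) {
    write_u64(os, part.nkeys);
    write_u64(os, part.width);
    if (part.nkeys) {
      part.f.save(os);
      part.V.save(os);
    }
  }
  if (!os) throw std::runtime_error("write failure on '" + path + "'");
}

inline Dictionary load_dictionary(const std::string& path) {
  std::ifstream is(path, std::ios::binary);
  if (!is) throw std::runtime_error("cannot open '" + path + "'");
  char magic[4];
  is.read(magic, 4);
  if (!is || std::string(magic, 4) != "SSHX")
    throw std::runtime_error("not an index file (bad magic)");
  uint64_t ver = read_u64(is);
  if (ver != kIndexVersion)
    throw std::runtime_error("unsupported index version " + std::to_string(ver));
  Dictionary d;
  d.cfg.k = uint32_t(read_u64(is));
  d.cfg.m = uint32_t(read_u64(is));
  d.cfg.canonical = read_u64(is) != 0;
  d.cfg.l = uint32_t(read_u64(is));
  d.cfg.L = uint32_t(read_u64(is));
  d.cfg.seed = read_u64(is);
  d.skew_enabled = read_u64(is) != 0;
  d.n = read_u64(is);
  d.z = read_u64(is);
  d.M = read_u64(is);
  d.max_bucket = read_u64(is);
  d.ps.N = read_u64(is);
  d.ps.bits.load(is);
  d.endpoints_ef.load(is);
  d.fmin.load(is);
  d.sizes.load(is);
  d.offsets.load(is);
  uint64_t np = read_u64(is);
  d.parts.assign(np, SkewPartition());
  for (uint64_t i = 0; i < np; ++i) {
    d.parts[i].nkeys = read_u64(is);
    d.parts[i].width = uint32_t(read_u64(is));
    if (d.parts[i].nkeys) {
      d.parts[i].f.load(is);
      d.parts[i].V.load(is);
    }
  }
  // endpoints are kept decoded for fast binary searches
  d.ps.endpoints.resize(d.endpoints_ef.n);
  for (uint64_t i = 0; i < d.endpoints_ef.n; ++i)
    d.ps.endpoints[i] = d.endpoints_ef.access(i);
  return d;
}

// ------------------------------------------------------- synthetic fixtures

// deterministic duplicate-free (canonical sense) random path cover; an
// optional motif implanted every `every` bases forces heavy minimizer buckets
inline std::vector<std::string> gen_cover_cpp(uint64_t p, uint64_t min_len,
                                              uint64_t max_len, uint32_t k,
                                              uint64_t seed,
                                              const std::string& motif,
                                              uint64_t every) {
  if (min_len < k) throw std::invalid_argument("min_len must be >= k");
  if (max_len < min_len) throw std::invalid_argument("max_len < min_len");
  std::mt19937_64 rng(seed);
  std::unordered_set<uint64_t> seen64;
  std::vector<kmer_t> seen_wide;
  std::vector<std::string> out;
  out.reserve(p);
  for (uint64_t s = 0; s < p; ++s) {
    uint64_t len = min_len + (max_len > min_len ? rng() % (max_len - min_len + 1) : 0);
    bool ok = false;
    std::string str;
    for (int attempt = 0; attempt < 100 && !ok; ++attempt) {
      str.resize(len);
      for (uint64_t i = 0; i < len; ++i) str[i] = "ACGT"[rng() & 3];
      if (!motif.empty() && every > 0)
        for (uint64_t at = 0; at + motif.size() <= len; at += every)
          str.replace(at, motif.size(), motif);
      // within-string + global canonical duplicate check
      ok = true;
      std::vector<uint64_t> add64;
      std::vector<kmer_t> addw;
      for (uint64_t wpos = 0; wpos + k <= len && ok; ++wpos) {
        kmer_t g = pack_kmer(str.data() + wpos, k);
        kmer_t rc = revcomp_kmer(g, k);
        kmer_t canon = g < rc ? g : rc;
        if (k <= 32) {
          uint64_t key = uint64_t(canon);
          if (seen64.count(key)) { ok = false; break; }
          add64.push_back(key);
        } else {
          addw.push_back(canon);
        }
      }
      if (ok && k <= 32) {
        std::sort(add64.begin(), add64.end());
        if (std::adjacent_find(add64.begin(), add64.end()) != add64.end()) ok = false;
        if (ok) for (uint64_t x : add64) seen64.insert(x);
      } else if (ok) {
        std::vector<kmer_t> merged(seen_wide);
        merged.insert(merged.end(), addw.begin(), addw.end());
        std::sort(merged.begin(), merged.end());
        if (std::adjacent_find(merged.begin(), merged.end()) != merged.end()) ok = false;
        if (ok) seen_wide.swap(merged);
      }
    }
    if (!ok)
      throw std::runtime_error("could not generate a duplicate-free string after 100 attempts");
    out.push_back(str);
  }
  return out;
}

inline std::string random_dna(uint64_t len, uint64_t seed) {
  std::mt19937_64 rng(seed);
  std::string s(len, 'A');
  for (uint64_t i = 0; i < len; ++i) s[i] = "ACGT"[rng() & 3];
  return s;
}

}  // namespace kdx
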