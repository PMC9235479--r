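// Rcpp bindings. All absolute offsets, identifiers and positions cross the
// R boundary as doubles (exact up to 2^53, far beyond any desk-scale index).
// Coordinates are 0-based half-open throughout, matching the index layout.

#include <Rcpp.h>
#include <map>
#include "dict.h"

using namespace Rcpp;
using namespace kdx;

static uint64_t as_u64(double x, const char* what) {
  if (x < 0 || x != x || x > 9007199254740992.0)
    stop("%s must be a non-negative integer below 2^53", what);
  return uint64_t(x);
}

// ------------------------------------------------------------------- dna

// [[Rcpp::export]]
IntegerVector cpp_encode_bases(std::string s) {
  IntegerVector out(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[i]);
    if (c < 0)
      stop("invalid base '%s' at position %d", std::string(1, s[i]).c_str(), int(i + 1));
    out[i] = c;
  }
  return out;
}

// [[Rcpp::export]]
std::string cpp_decode_bases(IntegerVector codes) {
  std::string s(codes.size(), 'A');
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    if (codes[i] < 0 || codes[i] > 3) stop("codes must be in 0..3");
    s[i] = code_base(codes[i]);
  }
  return s;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    std::string r(s.size(), 'A');
    for (size_t j = 0; j < s.size(); ++j) {
      int c = base_code(s[j]);
      if (c < 0)
        stop("invalid base '%s' at position %d", std::string(1, s[j]).c_str(), int(j + 1));
      r[s.size() - 1 - j] = code_base(c ^ 3);
    }
    out[i] = r;
  }
  return out;
}

// [[Rcpp::export]]
SEXP cpp_pack_dna(CharacterVector strings) {
  std::vector<std::string> v(strings.size());
  for (R_xlen_t i = 0; i < strings.size(); ++i) v[i] = as<std::string>(strings[i]);
  XPtr<PackedStrings> xp(new PackedStrings(pack_strings(v)), true);
  return xp;
}

// [[Rcpp::export]]
List cpp_packed_info(SEXP xp_) {
  XPtr<PackedStrings> xp(xp_);
  NumericVector ep(xp->endpoints.size());
  for (size_t i = 0; i < xp->endpoints.size(); ++i) ep[i] = double(xp->endpoints[i]);
  return List::create(_["N"] = double(xp->N), _["p"] = double(xp->p()),
                      _["endpoints"] = ep);
}

// [[Rcpp::export]]
CharacterVector cpp_unpack_dna(SEXP xp_) {
  XPtr<PackedStrings> xp(xp_);
  CharacterVector out(xp->p());
  for (uint64_t j = 0; j < xp->p(); ++j) {
    uint64_t beg = xp->endpoints[j], end = xp->endpoints[j + 1];
    std::string s(end - beg, 'A');
    for (uint64_t t = beg; t < end; ++t) s[t - beg] = code_base(xp->base_at(t));
    out[j] = s;
  }
  return out;
}

// [[Rcpp::export]]
std::string cpp_kmer_at(SEXP xp_, double t_, int k) {
  XPtr<PackedStrings> xp(xp_);
  uint64_t t = as_u64(t_, "t");
  if (t + uint64_t(k) > xp->N) stop("window [t, t+k) exceeds the packed strings");
  if (!xp->valid_window(t, uint32_t(k)))
    stop("alien window: [t, t+k) crosses a string endpoint");
  return unpack_kmer(xp->kmer_at(t, uint32_t(k)), uint32_t(k));
}

// ------------------------------------------------------------- minimizers

// [[Rcpp::export]]
CharacterVector cpp_mmer_hash(CharacterVector mmers, double seed) {
  uint64_t sd = as_u64(seed, "seed");
  CharacterVector out(mmers.size());
  char buf[17];
  for (R_xlen_t i = 0; i < mmers.size(); ++i) {
    std::string s = as<std::string>(mmers[i]);
    if (s.size() > 32) stop("m-mers longer than 32 bases are not supported");
    uint64_t h = mix64(uint64_t(pack_kmer(s.data(), uint32_t(s.size()))), sd);
    snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_minimizer(CharacterVector kmers, int m, double seed, bool canonical) {
  uint64_t sd = as_u64(seed, "seed");
  R_xlen_t nq = kmers.size();
  CharacterVector mmer(nq);
  NumericVector pos(nq);
  CharacterVector strand(nq);
  MmerArrays scratch;
  for (R_xlen_t i = 0; i < nq; ++i) {
    std::string s = as<std::string>(kmers[i]);
    uint32_t k = uint32_t(s.size());
    if (k < uint32_t(m)) stop("k-mer shorter than m");
    kmer_t g = pack_kmer(s.data(), k);
    WinMin wm = kmer_minimizer(g, k, uint32_t(m), sd, canonical, scratch);
    mmer[i] = unpack_kmer(kmer_t(wm.mmer), uint32_t(m));
    pos[i] = double(wm.pos);
    strand[i] = wm.rc ? "reverse" : "forward";
  }
  return DataFrame::create(_["mmer"] = mmer, _["pos"] = pos,
                           _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame cpp_parse_super_kmers(CharacterVector strings, int k, int m,
                                double seed, bool canonical) {
  std::vector<std::string> v(strings.size());
  for (R_xlen_t i = 0; i < strings.size(); ++i) {
    v[i] = as<std::string>(strings[i]);
    if (v[i].size() < size_t(k)) stop("string %d is shorter than k", int(i + 1));
  }
  if (m < 1 || m > k || m > 32) stop("need 1 <= m <= min(k, 32)");
  PackedStrings ps = pack_strings(v);
  std::vector<SuperKmer> sks =
      parse_super_kmers(ps, uint32_t(k), uint32_t(m), as_u64(seed, "seed"), canonical);
  R_xlen_t z = R_xlen_t(sks.size());
  NumericVector si(z), off(z), len(z), nk(z);
  CharacterVector mins(z);
  for (R_xlen_t i = 0; i < z; ++i) {
    si[i] = double(sks[i].string_index);
    off[i] = double(sks[i].offset);
    len[i] = double(sks[i].len);
    nk[i] = double(sks[i].len - uint32_t(k) + 1);
    mins[i] = unpack_kmer(kmer_t(sks[i].minimizer), uint32_t(m));
  }
  return DataFrame::create(_["string_index"] = si, _["offset"] = off,
                           _["length"] = len, _["n_kmers"] = nk,
                           _["minimizer"] = mins,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
double cpp_count_super_kmers(std::string s, int k, int m, double seed,
                             bool canonical) {
  std::vector<std::string> v{s};
  PackedStrings ps = pack_strings(v);
  return double(parse_super_kmers(ps, uint32_t(k), uint32_t(m),
                                  as_u64(seed, "seed"), canonical).size());
}

// ----------------------------------------------------------------- efseq

// [[Rcpp::export]]
SEXP cpp_ef_build(NumericVector values, double universe) {
  std::vector<uint64_t> v(values.size());
  for (R_xlen_t i = 0; i < values.size(); ++i) v[i] = as_u64(values[i], "values");
  XPtr<EliasFano> xp(new EliasFano(), true);
  xp->build(v, as_u64(universe, "universe"));
  return xp;
}

// [[Rcpp::export]]
NumericVector cpp_ef_access(SEXP xp_, NumericVector i) {
  XPtr<EliasFano> xp(xp_);
  NumericVector out(i.size());
  for (R_xlen_t t = 0; t < i.size(); ++t)
    out[t] = double(xp->access(as_u64(i[t], "i")));
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_ef_successor_rank(SEXP xp_, NumericVector x) {
  XPtr<EliasFano> xp(xp_);
  NumericVector out(x.size());
  for (R_xlen_t t = 0; t < x.size(); ++t)
    out[t] = double(xp->successor_rank(as_u64(x[t], "x")));
  return out;
}

// [[Rcpp::export]]
List cpp_ef_info(SEXP xp_) {
  XPtr<EliasFano> xp(xp_);
  return List::create(_["n"] = double(xp->n), _["universe"] = double(xp->universe),
                      _["low_width"] = int(xp->low_width),
                      _["payload_bits"] = double(xp->payload_bits()),
                      _["bound_bits"] = double(xp->bound_bits()));
}

// ----------------------------------------------------------------- mphf

// [[Rcpp::export]]
SEXP cpp_mphf_build(NumericVector keys, double seed) {
  std::vector<uint64_t> v(keys.size());
  for (R_xlen_t i = 0; i < keys.size(); ++i) v[i] = as_u64(keys[i], "keys");
  XPtr<Mphf> xp(new Mphf(), true);
  xp->build(v, as_u64(seed, "seed"));
  return xp;
}

// [[Rcpp::export]]
NumericVector cpp_mphf_eval(SEXP xp_, NumericVector x) {
  XPtr<Mphf> xp(xp_);
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = double(xp->eval(as_u64(x[i], "x")));
  return out;
}

// [[Rcpp::export]]
List cpp_mphf_info(SEXP xp_) {
  XPtr<Mphf> xp(xp_);
  return List::create(_["n_keys"] = double(xp->n), _["bits"] = double(xp->bits()),
                      _["levels"] = int(xp->levels.size()),
                      _["leftover"] = double(xp->leftover.size()));
}

// ------------------------------------------------------------- dictionary

// [[Rcpp::export]]
SEXP cpp_dict_build(CharacterVector strings, int k, int m, bool canonical,
                    int l, int L, double seed, bool skew, bool verify) {
  std::vector<std::string> v(strings.size());
  for (R_xlen_t i = 0; i < strings.size(); ++i) v[i] = as<std::string>(strings[i]);
  DictConfig cfg;
  cfg.k = uint32_t(k);
  cfg.m = uint32_t(m);
  cfg.canonical = canonical;
  cfg.l = uint32_t(l);
  cfg.L = uint32_t(L);
  cfg.seed = as_u64(seed, "seed");
  XPtr<Dictionary> xp(new Dictionary(build_dictionary(v, cfg, skew, verify)), true);
  return xp;
}

// [[Rcpp::export]]
List cpp_dict_params(SEXP xp_) {
  XPtr<Dictionary> d(xp_);
  return List::create(
      _["k"] = int(d->cfg.k), _["m"] = int(d->cfg.m),
      _["canonical"] = d->cfg.canonical, _["l"] = int(d->cfg.l),
      _["L"] = int(d->cfg.L), _["seed"] = double(d->cfg.seed),
      _["skew_enabled"] = d->skew_enabled, _["n"] = double(d->n),
      _["p"] = double(d->p()), _["N"] = double(d->N()), _["z"] = double(d->z),
      _["M"] = double(d->M), _["max_bucket"] = double(d->max_bucket));
}

static CharacterVector orient_chr(const std::vector<int>& o) {
  CharacterVector out(o.size());
  for (size_t i = 0; i < o.size(); ++i)
    out[i] = o[i] == 1 ? "forward" : (o[i] == -1 ? "reverse" : "none");
  return out;
}

static List counters_list(const Counters& c) {
  return List::create(
      _["f_evals"] = double(c.f_evals), _["skew_evals"] = double(c.skew_evals),
      _["bucket_scans"] = double(c.bucket_scans),
      _["superkmers_scanned"] = double(c.superkmers_scanned),
      _["kmer_comparisons"] = double(c.kmer_cmps),
      _["extension_attempts"] = double(c.ext_attempts),
      _["extensions"] = double(c.extensions));
}

// [[Rcpp::export]]
List cpp_dict_lookup(SEXP xp_, CharacterVector kmers) {
  XPtr<Dictionary> d(xp_);
  R_xlen_t nq = kmers.size();
  NumericVector id(nq), begin(nq), end(nq), t(nq), w(nq), j(nq);
  std::vector<int> orient(nq, 0);
  Counters c;
  uint32_t k = d->cfg.k;
  for (R_xlen_t i = 0; i < nq; ++i) {
    std::string s = as<std::string>(kmers[i]);
    if (s.size() != k) stop("query %d has length %d, expected k = %d",
                            int(i + 1), int(s.size()), int(k));
    bool valid = true;
    for (char ch : s)
      if (base_code(ch) < 0) { valid = false; break; }
    if (!valid) {  // non-ACGT query k-mers are reported absent
      id[i] = -1;
      continue;
    }
    LookupRes res = d->lookup_packed(pack_kmer(s.data(), k), &c);
    id[i] = double(res.id);
    orient[i] = res.orient;
    begin[i] = double(res.begin);
    end[i] = double(res.end);
    t[i] = double(res.t);
    w[i] = double(res.w);
    j[i] = double(res.j);
  }
  DataFrame df = DataFrame::create(
      _["id"] = id, _["orientation"] = orient_chr(orient), _["begin"] = begin,
      _["end"] = end, _["t"] = t, _["w"] = w, _["j"] = j,
      _["stringsAsFactors"] = false);
  return List::create(_["results"] = df, _["counters"] = counters_list(c));
}

// [[Rcpp::export]]
CharacterVector cpp_dict_access(SEXP xp_, NumericVector ids) {
  XPtr<Dictionary> d(xp_);
  CharacterVector out(ids.size());
  for (R_xlen_t i = 0; i < ids.size(); ++i)
    out[i] = d->access(as_u64(ids[i], "id"));
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_dict_iterate(SEXP xp_) {
  XPtr<Dictionary> d(xp_);
  CharacterVector out(R_xlen_t(d->n));
  uint32_t k = d->cfg.k;
  R_xlen_t idx = 0;
  for (uint64_t j = 0; j < d->p(); ++j)
    for (uint64_t t = d->ps.endpoints[j]; t + k <= d->ps.endpoints[j + 1]; ++t)
      out[idx++] = unpack_kmer(d->ps.kmer_at(t, k), k);
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_dict_valid_window(SEXP xp_, NumericVector t) {
  XPtr<Dictionary> d(xp_);
  LogicalVector out(t.size());
  for (R_xlen_t i = 0; i < t.size(); ++i)
    out[i] = d->ps.valid_window(as_u64(t[i], "t"), d->cfg.k);
  return out;
}

// [[Rcpp::export]]
List cpp_dict_stats(SEXP xp_) {
  XPtr<Dictionary> d(xp_);
  // bucket-size histogram from the prefix-summed sizes
  std::map<uint64_t, uint64_t> hist;
  for (uint64_t b = 0; b < d->M; ++b)
    ++hist[d->sizes.access(b + 1) - d->sizes.access(b)];
  NumericVector hsize(hist.size()), hcount(hist.size());
  R_xlen_t i = 0;
  for (auto& kv : hist) { hsize[i] = double(kv.first); hcount[i] = double(kv.second); ++i; }

  R_xlen_t np = R_xlen_t(d->parts.size());
  NumericVector pidx(np), pkeys(np), pwidth(np), pmphf(np), pvec(np);
  double skew_bits = 0;
  for (R_xlen_t s = 0; s < np; ++s) {
    const SkewPartition& part = d->parts[s];
    pidx[s] = double(d->cfg.l + s);
    pkeys[s] = double(part.nkeys);
    pwidth[s] = double(part.width);
    pmphf[s] = part.nkeys ? double(part.f.bits()) : 0.0;
    pvec[s] = double(part.V.bits());
    skew_bits += pmphf[s] + pvec[s];
  }
  return List::create(
      _["strings_bits"] = 2.0 * double(d->N()),
      _["endpoints_bits"] = double(d->endpoints_ef.payload_bits()),
      _["minimizer_mphf_bits"] = double(d->fmin.bits()),
      _["sizes_bits"] = double(d->sizes.payload_bits()),
      _["offsets_bits"] = double(d->offsets.bits()),
      _["offsets_width"] = int(d->offsets.width),
      _["skew_bits"] = skew_bits,
      _["skew_partitions"] = DataFrame::create(
          _["partition"] = pidx, _["n_keys"] = pkeys, _["width"] = pwidth,
          _["mphf_bits"] = pmphf, _["vector_bits"] = pvec),
      _["bucket_histogram"] = DataFrame::create(_["size"] = hsize, _["count"] = hcount));
}

// [[Rcpp::export]]
void cpp_dict_save(SEXP xp_, std::string path) {
  XPtr<Dictionary> d(xp_);
  save_dictionary(*d, path);
}

// [[Rcpp::export]]
SEXP cpp_dict_load(std::string path) {
  XPtr<Dictionary> xp(new Dictionary(load_dictionary(path)), true);
  return xp;
}

// [[Rcpp::export]]
IntegerVector cpp_skew_partition_of(NumericVector s, int l, int L) {
  IntegerVector out(s.size());
  for (R_xlen_t i = 0; i < s.size(); ++i) {
    uint64_t sz = as_u64(s[i], "s");
    if (sz < 1) stop("bucket size must be >= 1");
    out[i] = skew_partition_of(sz, uint32_t(l), uint32_t(L));
  }
  return out;
}

// ------------------------------------------------------------- streaming

// [[Rcpp::export]]
List cpp_stream_query(SEXP xp_, CharacterVector patterns, bool orientation_cache) {
  XPtr<Dictionary> d(xp_);
  std::vector<double> id, win, pat;
  std::vector<int> orient;
  Counters total;
  uint32_t k = d->cfg.k;
  for (R_xlen_t i = 0; i < patterns.size(); ++i) {
    std::string s = as<std::string>(patterns[i]);
    StreamOut so;  // fresh state per pattern
    stream_pattern(*d, s, orientation_cache, so);
    for (size_t wdx = 0; wdx < so.id.size(); ++wdx) {
      pat.push_back(double(i + 1));
      win.push_back(double(wdx));
      id.push_back(double(so.id[wdx]));
      orient.push_back(so.orient[wdx]);
    }
    total.f_evals += so.counters.f_evals;
    total.skew_evals += so.counters.skew_evals;
    total.bucket_scans += so.counters.bucket_scans;
    total.superkmers_scanned += so.counters.superkmers_scanned;
    total.kmer_cmps += so.counters.kmer_cmps;
    total.ext_attempts += so.counters.ext_attempts;
    total.extensions += so.counters.extensions;
  }
  DataFrame df = DataFrame::create(
      _["pattern"] = NumericVector(pat.begin(), pat.end()),
      _["window"] = NumericVector(win.begin(), win.end()),
      _["id"] = NumericVector(id.begin(), id.end()),
      _["orientation"] = orient_chr(orient), _["stringsAsFactors"] = false);
  return List::create(_["results"] = df, _["counters"] = counters_list(total));
}

// -------------------------------------------------------------- fixtures

// [[Rcpp::export]]
CharacterVector cpp_gen_cover(double p, double min_len, double max_len, int k,
                              double seed, std::string motif, double every) {
  std::vector<std::string> v =
      gen_cover_cpp(as_u64(p, "p"), as_u64(min_len, "min_len"),
                    as_u64(max_len, "max_len"), uint32_t(k),
                    as_u64(seed, "seed"), motif, as_u64(every, "every"));
  return wrap(v);
}

// [[Rcpp::export]]
std::string cpp_random_dna(double len, double seed) {
  return random_dna(as_u64(len, "len"), as_u64(seed, "seed"));
}
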