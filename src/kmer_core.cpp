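// Core sequence kernels: 2-bit packed canonical k-mer counting with
// sorted-array tables, merge joins, exact-match scanning of a reference
// against a k-mer set, rolling-hash mappability tracks, and small
// utilities for read extraction and alignment mismatch counting.
//
// k-mers with k <= 63 are packed into an unsigned __int128 (2 bits/base,
// A=0 C=1 G=2 T=3).  Tables cross the R boundary as three numeric vectors
// holding 42-bit words (exactly representable in doubles), sorted by code.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <string>
#include <map>
#include <set>
#include <cctype>
#include <cstdint>

using namespace Rcpp;

typedef unsigned __int128 u128;

static const int W = 42;                   // bits per exported word
static const double W_POW = 4398046511104.0; // 2^42

static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline u128 revcomp_code(u128 code, int k) {
  u128 rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (u128)(3 - (unsigned)(code & 3));
    code >>= 2;
  }
  return rc;
}

static inline void push_words(u128 code, std::vector<double>& w0,
                              std::vector<double>& w1, std::vector<double>& w2) {
  w0.push_back((double)(uint64_t)(code & (((u128)1 << W) - 1)));
  w1.push_back((double)(uint64_t)((code >> W) & (((u128)1 << W) - 1)));
  w2.push_back((double)(uint64_t)(code >> (2 * W)));
}

static inline u128 words_to_code(double a0, double a1, double a2) {
  return ((u128)(uint64_t)a2 << (2 * W)) | ((u128)(uint64_t)a1 << W) |
         (u128)(uint64_t)a0;
}

static std::vector<u128> codes_from_words(NumericVector w0, NumericVector w1,
                                          NumericVector w2) {
  size_t n = w0.size();
  std::vector<u128> v(n);
  for (size_t i = 0; i < n; ++i) v[i] = words_to_code(w0[i], w1[i], w2[i]);
  return v;
}

// Collect canonical k-mer codes of every clean window of every sequence.
static void collect_codes(const std::vector<std::string>& seqs, int k,
                          bool canonical, std::vector<u128>& out) {
  const u128 mask = (k == 64) ? ~(u128)0 : (((u128)1 << (2 * k)) - 1);
  for (const std::string& s : seqs) {
    int n = (int)s.size();
    if (n < k) continue;
    u128 fwd = 0, rc = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (u128)b) & mask;
      rc = (rc >> 2) | ((u128)(3 - b) << (2 * (k - 1)));
      if (++run >= k) out.push_back(canonical ? std::min(fwd, rc) : fwd);
    }
  }
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector reads, int k, bool canonical) {
  std::vector<std::string> seqs(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) seqs[i] = as<std::string>(reads[i]);
  std::vector<u128> inst;
  collect_codes(seqs, k, canonical, inst);
  std::sort(inst.begin(), inst.end());
  std::vector<double> w0, w1, w2;
  std::vector<int> cnt, gc;
  size_t i = 0, n = inst.size();
  while (i < n) {
    size_t j = i;
    while (j < n && inst[j] == inst[i]) ++j;
    push_words(inst[i], w0, w1, w2);
    cnt.push_back((int)(j - i));
    u128 c = inst[i];
    int g = 0;
    for (int t = 0; t < k; ++t) { unsigned b = (unsigned)(c & 3); if (b == 1 || b == 2) ++g; c >>= 2; }
    gc.push_back(g);
    i = j;
  }
  return List::create(_["w0"] = wrap(w0), _["w1"] = wrap(w1), _["w2"] = wrap(w2),
                      _["count"] = wrap(cnt), _["gc"] = wrap(gc),
                      _["n_instances"] = (double)n);
}

// Merge-join of two sorted code tables; returns 1-based index pairs.
// [[Rcpp::export]]
List cpp_join_tables(NumericVector a0, NumericVector a1, NumericVector a2,
                     NumericVector b0, NumericVector b1, NumericVector b2) {
  std::vector<u128> a = codes_from_words(a0, a1, a2);
  std::vector<u128> b = codes_from_words(b0, b1, b2);
  std::vector<int> ia, ib;
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) ++i;
    else if (b[j] < a[i]) ++j;
    else { ia.push_back((int)i + 1); ib.push_back((int)j + 1); ++i; ++j; }
  }
  return List::create(_["ia"] = wrap(ia), _["ib"] = wrap(ib));
}

// [[Rcpp::export]]
CharacterVector cpp_decode_kmers(NumericVector w0, NumericVector w1,
                                 NumericVector w2, int k) {
  static const char* B = "ACGT";
  R_xlen_t n = w0.size();
  CharacterVector out(n);
  std::string buf(k, 'A');
  for (R_xlen_t i = 0; i < n; ++i) {
    u128 c = words_to_code(w0[i], w1[i], w2[i]);
    for (int t = k - 1; t >= 0; --t) { buf[t] = B[(unsigned)(c & 3)]; c >>= 2; }
    out[i] = buf;
  }
  return out;
}

// Encode strings to (optionally canonical) codes; strings must be clean ACGT.
// [[Rcpp::export]]
List cpp_encode_kmers(CharacterVector kmers, int k, bool canonical) {
  std::vector<double> w0, w1, w2;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() != k) stop("k-mer length mismatch");
    u128 code = 0;
    for (int t = 0; t < k; ++t) {
      int b = base2bit(s[t]);
      if (b < 0) stop("non-ACGT base in k-mer");
      code = (code << 2) | (u128)b;
    }
    if (canonical) code = std::min(code, revcomp_code(code, k));
    push_words(code, w0, w1, w2);
  }
  return List::create(_["w0"] = wrap(w0), _["w1"] = wrap(w1), _["w2"] = wrap(w2));
}

// Positions (1-based window starts) in each sequence whose canonical k-mer
// is a member of the sorted code set.
// [[Rcpp::export]]
List cpp_ref_kmer_hits(CharacterVector seqs, int k, NumericVector s0,
                       NumericVector s1, NumericVector s2) {
  std::vector<u128> set = codes_from_words(s0, s1, s2);
  std::vector<int> seq_idx, pos;
  const u128 mask = (((u128)1 << (2 * k)) - 1);
  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    std::string s = as<std::string>(seqs[si]);
    int n = (int)s.size();
    u128 fwd = 0, rc = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (u128)b) & mask;
      rc = (rc >> 2) | ((u128)(3 - b) << (2 * (k - 1)));
      if (++run >= k) {
        u128 c = std::min(fwd, rc);
        if (std::binary_search(set.begin(), set.end(), c)) {
          seq_idx.push_back((int)si + 1);
          pos.push_back(i - k + 2);
        }
      }
    }
  }
  return List::create(_["seq"] = wrap(seq_idx), _["pos"] = wrap(pos));
}

// ---- mappability ------------------------------------------------------

struct HashedPos { uint64_t h1, h2; int scaf, pos; };
static bool hp_less(const HashedPos& a, const HashedPos& b) {
  if (a.h1 != b.h1) return a.h1 < b.h1;
  return a.h2 < b.h2;
}
static bool hp_eq(const HashedPos& a, const HashedPos& b) {
  return a.h1 == b.h1 && a.h2 == b.h2;
}

// Exact-match mappability via double 64-bit rolling hashes of the canonical
// K-mer (collision probability negligible at desk scale).
// mode: "scaffold" -> 1 if the K-mer occurs only within this scaffold;
//       "unique"   -> 1 if the K-mer occurs exactly once genome-wide.
// [[Rcpp::export]]
List cpp_mappability(CharacterVector seqs, int K, std::string mode) {
  const uint64_t P1 = 1000000007ULL, P2 = 998244353ULL;
  uint64_t p1K = 1, p2K = 1; // P^(K-1)
  for (int i = 0; i < K - 1; ++i) { p1K *= P1; p2K *= P2; }
  // modular inverses of the (odd) bases mod 2^64, via Newton iteration
  uint64_t i1 = P1, i2 = P2;
  for (int t = 0; t < 6; ++t) { i1 *= 2 - P1 * i1; i2 *= 2 - P2 * i2; }
  std::vector<HashedPos> all;
  std::vector<std::string> ss(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) ss[i] = as<std::string>(seqs[i]);

  for (size_t si = 0; si < ss.size(); ++si) {
    const std::string& s = ss[si];
    int n = (int)s.size();
    if (n < K) continue;
    // prefix-scan with reset at non-ACGT
    int i = 0;
    while (i + K <= n) {
      // find clean window start
      int bad = -1;
      for (int t = i; t < i + K; ++t) if (base2bit(s[t]) < 0) { bad = t; break; }
      if (bad >= 0) { i = bad + 1; continue; }
      // initialise hashes at window i
      uint64_t f1 = 0, f2 = 0, r1 = 0, r2 = 0;
      for (int t = 0; t < K; ++t) {
        uint64_t b = (uint64_t)base2bit(s[i + t]);
        f1 = f1 * P1 + b; f2 = f2 * P2 + b;
      }
      for (int t = K - 1; t >= 0; --t) {
        uint64_t b = 3 - (uint64_t)base2bit(s[i + t]);
        r1 = r1 * P1 + b; r2 = r2 * P2 + b;
      }
      while (true) {
        uint64_t h1 = f1, h2 = f2;
        if (r1 < f1 || (r1 == f1 && r2 < f2)) { h1 = r1; h2 = r2; }
        all.push_back({h1, h2, (int)si, i});
        if (i + K >= n) { i = n; break; }
        int bnew = base2bit(s[i + K]);
        if (bnew < 0) { i = i + K + 1; break; }
        uint64_t out = (uint64_t)base2bit(s[i]);
        f1 = (f1 - out * p1K) * P1 + (uint64_t)bnew;
        f2 = (f2 - out * p2K) * P2 + (uint64_t)bnew;
        // rc hash: drop its trailing char comp(s[i]) (weight 1), divide by P
        // (exact via the modular inverse), prepend comp(bnew) at weight P^(K-1)
        r1 = (r1 - (3 - out)) * i1 + (3 - (uint64_t)bnew) * p1K;
        r2 = (r2 - (3 - out)) * i2 + (3 - (uint64_t)bnew) * p2K;
        ++i;
      }
    }
  }

  std::sort(all.begin(), all.end(), hp_less);
  // verdict per group
  std::vector<std::vector<int>> tracks(ss.size());
  for (size_t si = 0; si < ss.size(); ++si) {
    int len = (int)ss[si].size() - K + 1;
    tracks[si].assign(std::max(len, 0), 0);
  }
  size_t g = 0;
  bool scaffold_mode = (mode == "scaffold");
  while (g < all.size()) {
    size_t j = g;
    bool one_scaf = true;
    while (j < all.size() && hp_eq(all[j], all[g])) {
      if (all[j].scaf != all[g].scaf) one_scaf = false;
      ++j;
    }
    bool ok = scaffold_mode ? one_scaf : (j - g == 1);
    if (ok)
      for (size_t t = g; t < j; ++t) tracks[all[t].scaf][all[t].pos] = 1;
    g = j;
  }
  List out(ss.size());
  for (size_t si = 0; si < ss.size(); ++si) out[si] = wrap(tracks[si]);
  return out;
}

// Approximate mappability with up to E substitutions: pigeonhole seeds +
// Hamming verification.  Desk-scale only (quadratic in seed-bucket sizes).
// [[Rcpp::export]]
List cpp_mappability_approx(CharacterVector seqs, int K, int E, std::string mode) {
  std::vector<std::string> ss(seqs.size());
  size_t total = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) { ss[i] = as<std::string>(seqs[i]); total += ss[i].size(); }
  struct Win { int scaf, pos; };
  std::vector<Win> wins;
  std::vector<std::string> fwd, rc;
  for (size_t si = 0; si < ss.size(); ++si) {
    const std::string& s = ss[si];
    for (int i = 0; i + K <= (int)s.size(); ++i) {
      bool clean = true;
      for (int t = i; t < i + K; ++t) if (base2bit(s[t]) < 0) { clean = false; break; }
      if (!clean) continue;
      std::string w = s.substr(i, K), r(K, 'A');
      for (int t = 0; t < K; ++t) {
        static const char* B = "ACGT";
        r[K - 1 - t] = B[3 - base2bit(w[t])];
      }
      wins.push_back({(int)si, i});
      fwd.push_back(w); rc.push_back(r);
    }
  }
  int n = (int)wins.size();
  int L = K / (E + 1);
  // seed index: map seed string -> list of (window, slot, strand)
  std::map<std::string, std::vector<int>> index; // encode (win*2+strand)*(E+1)+slot
  for (int w = 0; w < n; ++w)
    for (int sl = 0; sl <= E; ++sl)
      index[fwd[w].substr(sl * L, L)].push_back(w);
  auto hamming_le = [&](const std::string& a, const std::string& b, int e) {
    int d = 0;
    for (int t = 0; t < (int)a.size(); ++t) { if (a[t] != b[t]) if (++d > e) return false; }
    return true;
  };
  // occurrence scaffolds per window (a window always matches itself)
  std::vector<std::vector<int>> tracks(ss.size());
  for (size_t si = 0; si < ss.size(); ++si)
    tracks[si].assign(std::max((int)ss[si].size() - K + 1, 0), 0);
  bool scaffold_mode = (mode == "scaffold");
  for (int w = 0; w < n; ++w) {
    bool other_scaf = false; int n_occ = 1;
    std::set<int> cand;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& q = strand ? rc[w] : fwd[w];
      for (int sl = 0; sl <= E; ++sl) {
        auto it = index.find(q.substr(sl * L, L));
        if (it == index.end()) continue;
        for (int c : it->second) cand.insert(c * 2 + strand);
      }
    }
    for (int cs : cand) {
      int c = cs / 2, strand = cs % 2;
      if (c == w) continue; // same locus, either orientation
      const std::string& q = strand ? rc[w] : fwd[w];
      if (hamming_le(q, fwd[c], E)) {
        ++n_occ;
        if (wins[c].scaf != wins[w].scaf) other_scaf = true;
      }
    }
    bool ok = scaffold_mode ? !other_scaf : (n_occ == 1);
    if (ok) tracks[wins[w].scaf][wins[w].pos] = 1;
  }
  List out(ss.size());
  for (size_t si = 0; si < ss.size(); ++si) out[si] = wrap(tracks[si]);
  return out;
}

// ---- read extraction --------------------------------------------------

// Extract reads from chromosome sequences and inject substitution errors
// using R's RNG (so set.seed() governs reproducibility).
// [[Rcpp::export]]
CharacterVector cpp_extract_reads(CharacterVector chromseqs, IntegerVector chrom,
                                  IntegerVector start, int read_length,
                                  LogicalVector revcomp, double error_rate) {
  static const char* B = "ACGT";
  std::vector<std::string> seqs(chromseqs.size());
  for (R_xlen_t i = 0; i < chromseqs.size(); ++i) seqs[i] = as<std::string>(chromseqs[i]);
  R_xlen_t n = chrom.size();
  CharacterVector out(n);
  RNGScope scope;
  for (R_xlen_t i = 0; i < n; ++i) {
    const std::string& s = seqs[chrom[i] - 1];
    std::string r = s.substr(start[i] - 1, read_length);
    if (revcomp[i]) {
      std::string t(r.rbegin(), r.rend());
      for (char& c : t) { int b = base2bit(c); c = (b < 0) ? 'N' : B[3 - b]; }
      r = t;
    }
    if (error_rate > 0) {
      for (int t = 0; t < (int)r.size(); ++t) {
        if (unif_rand() < error_rate) {
          int b = base2bit(r[t]);
          int nb = (int)(unif_rand() * 3.0); if (nb > 2) nb = 2;
          if (b >= 0) r[t] = B[(b + 1 + nb) % 4];
        }
      }
    }
    out[i] = r;
  }
  return out;
}

// Mismatch and column counts over gapless alignment blocks.
// Query coordinates are on the + strand; for strand == '-' the query block
// is reverse-complemented before comparison (per PSL convention the target
// runs forward).
// [[Rcpp::export]]
IntegerVector cpp_count_mismatches(std::string target, std::string query,
                                   IntegerVector tstart, IntegerVector qstart,
                                   IntegerVector len, bool minus) {
  long mm = 0, cols = 0;
  for (R_xlen_t b = 0; b < tstart.size(); ++b) {
    int ts = tstart[b], qs = qstart[b], L = len[b];
    for (int i = 0; i < L; ++i) {
      char tc = target[ts + i];
      char qc;
      if (!minus) qc = query[qs + i];
      else {
        static const char* B = "ACGT";
        char raw = query[qs + L - 1 - i];
        int bb = base2bit(raw);
        qc = (bb < 0) ? 'N' : B[3 - bb];
      }
      ++cols;
      if (toupper(tc) != toupper(qc)) ++mm;
    }
  }
  return IntegerVector::create((int)mm, (int)cols);
}
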