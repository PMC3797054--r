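// Low-level sequence kernels: de Bruijn unitig construction, seeded
// pseudo-alignment with a mismatch budget, exact-containment scanning,
// ungapped seed-and-extend homology search (protein and nucleotide),
// and genome seed matching.  All coordinates are 0-based half-open.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cstring>
#include <climits>
#include <deque>

using namespace Rcpp;

typedef unsigned __int128 u128;

static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}
static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    int b = base2bit(r[i]);
    r[i] = (b < 0) ? 'N' : BITS2BASE[3 - b];
  }
  return r;
}

struct Hash128 {
  size_t operator()(const u128& x) const {
    uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
    lo *= 0x9E3779B97F4A7C15ULL; lo ^= lo >> 32;
    hi *= 0xC2B2AE3D27D4EB4FULL; hi ^= hi >> 29;
    return (size_t)(lo ^ (hi * 0x165667B19E3779F9ULL));
  }
};

// ---------------------------------------------------------------------------
// de Bruijn unitigs over canonical k-mers
// ---------------------------------------------------------------------------

struct Hash64 {
  size_t operator()(const uint64_t& x) const {
    uint64_t h = x;
    h *= 0x9E3779B97F4A7C15ULL; h ^= h >> 32;
    h *= 0xC2B2AE3D27D4EB4FULL; h ^= h >> 29;
    return (size_t)h;
  }
};

// fast reverse complement of a 2-bit packed k-mer
static inline uint64_t rc_bits(uint64_t x, int k) {
  x = ~x;
  x = ((x & 0x3333333333333333ULL) << 2) | ((x >> 2) & 0x3333333333333333ULL);
  x = ((x & 0x0F0F0F0F0F0F0F0FULL) << 4) | ((x >> 4) & 0x0F0F0F0F0F0F0F0FULL);
  x = __builtin_bswap64(x);
  return x >> (64 - 2 * k);
}
static inline u128 rc_bits(u128 x, int k) {
  uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
  // full 128-bit reverse complement, then shift down to 2k bits
  u128 r = ((u128)rc_bits(lo, 32) << 64) | (u128)rc_bits(hi, 32);
  return r >> (128 - 2 * k);
}

template <typename K>
struct UnitigBuilder {
  int k;
  K mask;
  typedef typename std::conditional<sizeof(K) == 8, Hash64, Hash128>::type H;
  typedef std::unordered_set<K, H> KSet;

  struct OKmer { K f, r; };
  inline K canon(const OKmer& o) const { return o.f < o.r ? o.f : o.r; }
  inline OKmer flip(const OKmer& o) const { return OKmer{o.r, o.f}; }
  inline OKmer step(const OKmer& o, int b) const {
    OKmer n;
    n.f = ((o.f << 2) | (K)b) & mask;
    n.r = (o.r >> 2) | ((K)(3 - b) << (2 * (k - 1)));
    return n;
  }
  inline int out_bases(const OKmer& o, const KSet& S, int* bases) const {
    int n = 0;
    for (int b = 0; b < 4; ++b) {
      OKmer nx = step(o, b);
      if (S.count(canon(nx))) bases[n++] = b;
    }
    return n;
  }
  std::string decode(K f) const {
    std::string s(k, 'N');
    for (int i = 0; i < k; ++i)
      s[i] = BITS2BASE[(int)((f >> (2 * (k - 1 - i))) & 3)];
    return s;
  }

  std::vector<std::string> run(SEXP reads, int min_count, double err_ratio) {
    // pass 1: count canonical k-mers
    std::unordered_map<K, uint32_t, H> counts;
    const R_xlen_t n = Rf_xlength(reads);
    for (R_xlen_t i = 0; i < n; ++i) {
      const char* s = CHAR(STRING_ELT(reads, i));
      int len = (int)std::strlen(s);
      if (len < k) continue;
      K f = 0, r = 0;
      int run_len = 0;
      for (int j = 0; j < len; ++j) {
        int b = base2bit(s[j]);
        if (b < 0) { run_len = 0; f = 0; r = 0; continue; }
        f = ((f << 2) | (K)b) & mask;
        r = (r >> 2) | ((K)(3 - b) << (2 * (k - 1)));
        if (++run_len >= k) {
          K c = f < r ? f : r;
          ++counts[c];
        }
      }
    }

    // relative branch pruning: drop a k-mer whose count is below err_ratio
    // times the best count among k-mers differing in one terminal base
    // (the same-position alternatives an error creates at high coverage)
    if (err_ratio > 0) {
      std::vector<K> drop;
      for (const auto& kv : counts) {
        const K c = kv.first;
        const uint32_t cnt = kv.second;
        const K R = rc_bits(c, k);
        uint32_t mx = cnt;
        for (int b = 0; b < 4; ++b) {
          // vary the last base of c
          K z1 = (c & ~(K)3) | (K)b;
          K z1r = (R & (mask >> 2)) | ((K)(3 - b) << (2 * (k - 1)));
          K cz1 = z1 < z1r ? z1 : z1r;
          auto it1 = counts.find(cz1);
          if (it1 != counts.end() && it1->second > mx) mx = it1->second;
          // vary the first base of c
          K z2 = ((K)b << (2 * (k - 1))) | (c & (mask >> 2));
          K z2r = (R & ~(K)3) | (K)(3 - b);
          K cz2 = z2 < z2r ? z2 : z2r;
          auto it2 = counts.find(cz2);
          if (it2 != counts.end() && it2->second > mx) mx = it2->second;
        }
        if ((double)cnt < err_ratio * (double)mx) drop.push_back(c);
      }
      for (const K& c : drop) counts.erase(c);
    }

    KSet S;
    S.reserve(counts.size());
    std::vector<K> solids;
    for (auto& kv : counts)
      if ((int)kv.second >= min_count) {
        S.insert(kv.first); solids.push_back(kv.first);
      }
    counts.clear();
    std::sort(solids.begin(), solids.end());

    KSet visited;
    visited.reserve(S.size());
    std::vector<std::string> out;
    int bases[4], bases2[4];
    const size_t maxsteps = S.size() + 2;

    for (const K& c : solids) {
      if (visited.count(c)) continue;
      OKmer cur;
      cur.f = c;
      {
        std::string rs = revcomp_str(decode(c));
        K r = 0;
        for (int j = 0; j < k; ++j) r = (r << 2) | (K)base2bit(rs[j]);
        cur.r = r;
      }
      // walk backward to the unitig start
      size_t steps = 0;
      while (steps++ < maxsteps) {
        OKmer rev = flip(cur);
        int np = out_bases(rev, S, bases);
        if (np != 1) break;
        OKmer pred = flip(step(rev, bases[0]));
        if (out_bases(pred, S, bases2) != 1) break;
        if (canon(pred) == c) break;  // circular component
        cur = pred;
      }
      // walk forward, emitting the unitig
      std::string seq = decode(cur.f);
      visited.insert(canon(cur));
      while (true) {
        int no = out_bases(cur, S, bases);
        if (no != 1) break;
        OKmer nxt = step(cur, bases[0]);
        if (out_bases(flip(nxt), S, bases2) != 1) break;  // in-degree != 1
        K cn = canon(nxt);
        if (visited.count(cn)) break;
        visited.insert(cn);
        seq.push_back(BITS2BASE[bases[0]]);
        cur = nxt;
      }
      std::string rc = revcomp_str(seq);
      out.push_back(seq <= rc ? seq : rc);
    }
    std::sort(out.begin(), out.end());
    out.erase(std::unique(out.begin(), out.end()), out.end());
    return out;
  }
};

// [[Rcpp::export]]
CharacterVector rcpp_build_unitigs(CharacterVector reads, int k, int min_count,
                                   double err_ratio) {
  if (k < 2 || k > 63) stop("k must be in [2, 63]");
  std::vector<std::string> out;
  if (k <= 31) {
    UnitigBuilder<uint64_t> b;
    b.k = k;
    b.mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    out = b.run(reads, min_count, err_ratio);
  } else {
    UnitigBuilder<u128> b;
    b.k = k;
    b.mask = (((u128)1) << (2 * k)) - 1;
    out = b.run(reads, min_count, err_ratio);
  }
  return wrap(out);
}

// ---------------------------------------------------------------------------
// seeded pseudo-alignment, <= max_mm mismatches, both strands
// ---------------------------------------------------------------------------

static inline bool encode_window(const char* s, int w, uint64_t& code) {
  code = 0;
  for (int i = 0; i < w; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t)b;
  }
  return true;
}

// [[Rcpp::export]]
List rcpp_pseudo_align(CharacterVector reads, CharacterVector refs,
                       int max_mm, int seed_len) {
  const int nref = refs.size();
  std::vector<const char*> rs(nref);
  std::vector<int> rl(nref);
  for (int i = 0; i < nref; ++i) {
    rs[i] = CHAR(STRING_ELT(refs, i));
    rl[i] = (int)std::strlen(rs[i]);
  }
  // index every seed_len-mer of every reference
  std::unordered_map<uint64_t, std::vector<uint64_t>> idx;
  for (int r = 0; r < nref; ++r) {
    uint64_t code = 0;
    const uint64_t mask = (seed_len >= 32) ? ~0ULL : ((1ULL << (2 * seed_len)) - 1);
    int run = 0;
    for (int j = 0; j < rl[r]; ++j) {
      int b = base2bit(rs[r][j]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run >= seed_len)
        idx[code].push_back(((uint64_t)r << 32) | (uint64_t)(j - seed_len + 1));
    }
  }

  const R_xlen_t n = reads.size();
  IntegerVector out_ref(n, NA_INTEGER), out_pos(n, NA_INTEGER),
      out_strand(n, NA_INTEGER), out_mm(n, NA_INTEGER), out_status(n);
  std::string rcbuf;
  std::vector<uint64_t> cands;

  for (R_xlen_t i = 0; i < n; ++i) {
    const char* fwd = CHAR(STRING_ELT(reads, i));
    int L = (int)std::strlen(fwd);
    if (L < seed_len) { out_status[i] = 2; continue; }
    rcbuf.assign(fwd, L);
    rcbuf = revcomp_str(rcbuf);
    int offs[3] = {0, (L - seed_len) / 2, L - seed_len};
    int noff = (offs[1] == offs[0] || offs[1] == offs[2]) ? 2 : 3;
    if (offs[2] == offs[0]) noff = 1;

    cands.clear();
    for (int st = 0; st < 2; ++st) {
      const char* q = (st == 0) ? fwd : rcbuf.c_str();
      for (int oi = 0; oi < noff; ++oi) {
        int o = (oi == 1 && noff == 2) ? offs[2] : offs[oi];
        uint64_t code;
        if (!encode_window(q + o, seed_len, code)) continue;
        auto it = idx.find(code);
        if (it == idx.end()) continue;
        for (uint64_t h : it->second) {
          int r = (int)(h >> 32), p = (int)(h & 0xFFFFFFFFULL) - o;
          if (p < 0 || p + L > rl[r]) continue;
          cands.push_back(((uint64_t)st << 62) | ((uint64_t)r << 32) | (uint64_t)p);
        }
      }
    }
    std::sort(cands.begin(), cands.end());
    cands.erase(std::unique(cands.begin(), cands.end()), cands.end());

    int best_mm = max_mm + 1;
    int best_ref = -1, best_pos = -1, best_st = 0;
    std::unordered_set<int> best_refs;
    for (uint64_t cd : cands) {
      int st = (int)(cd >> 62), r = (int)((cd >> 32) & 0x3FFFFFFF),
          p = (int)(cd & 0xFFFFFFFFULL);
      const char* q = (st == 0) ? fwd : rcbuf.c_str();
      const char* t = rs[r] + p;
      int mm = 0;
      for (int j = 0; j < L; ++j) {
        if (q[j] != t[j] && ++mm > max_mm) break;
      }
      if (mm > max_mm) continue;
      if (mm < best_mm) {
        best_mm = mm; best_refs.clear(); best_refs.insert(r);
        best_ref = r; best_pos = p; best_st = st;
      } else if (mm == best_mm) {
        best_refs.insert(r);
        // deterministic tie-break: smallest (ref, pos, strand)
        if (r < best_ref || (r == best_ref && (p < best_pos ||
            (p == best_pos && st < best_st)))) {
          best_ref = r; best_pos = p; best_st = st;
        }
      }
    }
    if (best_mm > max_mm) {
      out_status[i] = 2;  // unaligned
    } else if (best_refs.size() > 1) {
      out_status[i] = 1;  // ambiguous across transcripts
      out_mm[i] = best_mm;
    } else {
      out_status[i] = 0;
      out_ref[i] = best_ref + 1;
      out_pos[i] = best_pos;
      out_strand[i] = best_st == 0 ? 1 : -1;
      out_mm[i] = best_mm;
    }
  }
  return List::create(_["ref"] = out_ref, _["pos"] = out_pos,
                      _["strand"] = out_strand, _["mismatches"] = out_mm,
                      _["status"] = out_status);
}

// ---------------------------------------------------------------------------
// exact containment removal (either strand); antichain under substring order
// ---------------------------------------------------------------------------

// shared helper: is `q` (length m) a substring of the kept contig set, using a
// strided w-mer index over kept sequences?  Returns index of a containing kept
// sequence (into `kept`), or -1.
struct StrideIndex {
  int w;
  std::unordered_map<uint64_t, std::vector<uint64_t>> map;  // code -> (id<<32|pos)
  std::vector<const std::string*> seqs;

  void add(const std::string& s) {
    int id = (int)seqs.size();
    seqs.push_back(&s);
    uint64_t code;
    int len = (int)s.size();
    for (int p = 0; p + w <= len; p += w)
      if (encode_window(s.c_str() + p, w, code))
        map[code].push_back(((uint64_t)id << 32) | (uint64_t)p);
    // tail w-mer so short sequences are represented
    int tail = len - w;
    if (tail > 0 && tail % w != 0 && encode_window(s.c_str() + tail, w, code))
      map[code].push_back(((uint64_t)id << 32) | (uint64_t)tail);
  }

  // find a kept sequence containing q as an exact substring (given orientation)
  int find(const std::string& q) const {
    int m = (int)q.size();
    if (m < w) return -1;
    uint64_t code = 0;
    const uint64_t mask = (w >= 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
    int run = 0;
    for (int j = 0; j < m; ++j) {
      int b = base2bit(q[j]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run < w) continue;
      int qoff = j - w + 1;
      auto it = map.find(code);
      if (it == map.end()) continue;
      for (uint64_t h : it->second) {
        int id = (int)(h >> 32), p = (int)(h & 0xFFFFFFFFULL);
        int o = p - qoff;
        const std::string& K = *seqs[id];
        if (o < 0 || o + m > (int)K.size()) continue;
        if (std::memcmp(K.c_str() + o, q.c_str(), m) == 0) return id;
      }
    }
    return -1;
  }
};

// [[Rcpp::export]]
LogicalVector rcpp_contained_keep(CharacterVector seqs) {
  const int n = seqs.size();
  LogicalVector keep(n, false);
  if (n == 0) return keep;
  std::vector<std::string> ss(n);
  std::vector<int> ord(n);
  int minlen = INT_MAX;
  for (int i = 0; i < n; ++i) {
    ss[i] = std::string(CHAR(STRING_ELT(seqs, i)));
    minlen = std::min(minlen, (int)ss[i].size());
    ord[i] = i;
  }
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (ss[a].size() != ss[b].size()) return ss[a].size() > ss[b].size();
    return ss[a] < ss[b];
  });

  if (minlen < 7 || n <= 64) {
    // brute force for tiny pools / very short contigs
    std::vector<int> kept;
    for (int oi : ord) {
      const std::string& q = ss[oi];
      std::string qr = revcomp_str(q);
      bool contained = false;
      for (int kj : kept) {
        const std::string& K = ss[kj];
        if (K.size() < q.size()) continue;
        if (K.find(q) != std::string::npos || K.find(qr) != std::string::npos) {
          contained = true; break;
        }
      }
      if (!contained) { keep[oi] = true; kept.push_back(oi); }
    }
    return keep;
  }

  StrideIndex idx;
  idx.w = std::min(31, (minlen + 1) / 2);
  std::deque<std::string> store;  // stable storage for kept sequences
  for (int oi : ord) {
    const std::string& q = ss[oi];
    std::string qr = revcomp_str(q);
    if (idx.find(q) >= 0 || idx.find(qr) >= 0) continue;
    keep[oi] = true;
    store.push_back(q);
    idx.add(store.back());
  }
  return keep;
}

// [[Rcpp::export]]
DataFrame rcpp_substring_hits(CharacterVector queries, CharacterVector subjects) {
  const int nq = queries.size(), ns = subjects.size();
  std::vector<std::string> qs(nq), sj(ns);
  int minq = INT_MAX;
  for (int i = 0; i < nq; ++i) { qs[i] = CHAR(STRING_ELT(queries, i)); minq = std::min(minq, (int)qs[i].size()); }
  for (int i = 0; i < ns; ++i) sj[i] = CHAR(STRING_ELT(subjects, i));
  std::vector<int> out_q, out_s;

  if (nq == 0 || ns == 0) {
    return DataFrame::create(_["query"] = IntegerVector(0), _["subject"] = IntegerVector(0));
  }
  if (minq < 7) {
    for (int i = 0; i < nq; ++i) {
      std::string qr = revcomp_str(qs[i]);
      for (int j = 0; j < ns; ++j)
        if (sj[j].find(qs[i]) != std::string::npos ||
            sj[j].find(qr) != std::string::npos) {
          out_q.push_back(i + 1); out_s.push_back(j + 1);
        }
    }
  } else {
    // index all w-mers of subjects (stride w), query every w-mer of each query
    StrideIndex idx;
    idx.w = std::min(31, (minq + 1) / 2);
    for (int j = 0; j < ns; ++j) idx.add(sj[j]);
    for (int i = 0; i < nq; ++i) {
      std::unordered_set<int> found;
      // collect all subjects containing the query (either strand)
      for (int orient = 0; orient < 2; ++orient) {
        std::string q = orient == 0 ? qs[i] : revcomp_str(qs[i]);
        int m = (int)q.size();
        uint64_t code = 0;
        const int w = idx.w;
        const uint64_t mask = (w >= 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
        int run = 0;
        for (int jj = 0; jj < m; ++jj) {
          int b = base2bit(q[jj]);
          if (b < 0) { run = 0; code = 0; continue; }
          code = ((code << 2) | (uint64_t)b) & mask;
          if (++run < w) continue;
          int qoff = jj - w + 1;
          auto it = idx.map.find(code);
          if (it == idx.map.end()) continue;
          for (uint64_t h : it->second) {
            int id = (int)(h >> 32), p = (int)(h & 0xFFFFFFFFULL);
            if (found.count(id)) continue;
            int o = p - qoff;
            const std::string& K = *idx.seqs[id];
            if (o < 0 || o + m > (int)K.size()) continue;
            if (std::memcmp(K.c_str() + o, q.c_str(), m) == 0) found.insert(id);
          }
        }
      }
      for (int id : found) { out_q.push_back(i + 1); out_s.push_back(id + 1); }
    }
  }
  return DataFrame::create(_["query"] = wrap(out_q), _["subject"] = wrap(out_s));
}

// [[Rcpp::export]]
LogicalVector rcpp_mark_unique_kmers(CharacterVector seqs, int k) {
  const int n = seqs.size();
  if (k < 2 || k > 63) stop("k must be in [2, 63]");
  const u128 MASK = (((u128)1) << (2 * k)) - 1;
  std::unordered_map<u128, uint32_t, Hash128> counts;
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = CHAR(STRING_ELT(seqs, i));
  for (int i = 0; i < n; ++i) {
    const std::string& s = ss[i];
    u128 f = 0, r = 0; int run = 0;
    for (size_t j = 0; j < s.size(); ++j) {
      int b = base2bit(s[j]);
      if (b < 0) { run = 0; f = 0; r = 0; continue; }
      f = ((f << 2) | (u128)b) & MASK;
      r = (r >> 2) | ((u128)(3 - b) << (2 * (k - 1)));
      if (++run >= k) {
        u128 c = f < r ? f : r;
        auto it = counts.find(c);
        if (it == counts.end()) counts[c] = 1; else if (it->second < 2) it->second = 2;
      }
    }
  }
  LogicalVector ok(n);
  for (int i = 0; i < n; ++i) {
    const std::string& s = ss[i];
    if ((int)s.size() < k) { ok[i] = false; continue; }
    bool uniq = true;
    u128 f = 0, r = 0; int run = 0; int nk = 0;
    for (size_t j = 0; j < s.size() && uniq; ++j) {
      int b = base2bit(s[j]);
      if (b < 0) { run = 0; f = 0; r = 0; continue; }
      f = ((f << 2) | (u128)b) & MASK;
      r = (r >> 2) | ((u128)(3 - b) << (2 * (k - 1)));
      if (++run >= k) {
        ++nk;
        u128 c = f < r ? f : r;
        if (counts[c] > 1) uniq = false;
      }
    }
    ok[i] = uniq && nk > 0;
  }
  return ok;
}

// ---------------------------------------------------------------------------
// ungapped seed-and-extend protein search (exact word seeds, X-drop)
// ---------------------------------------------------------------------------

struct Hsp {
  int score = INT_MIN;
  int qs = 0, qe = 0, ss = 0, se = 0;
};

// [[Rcpp::export]]
DataFrame rcpp_protein_search(CharacterVector queries, CharacterVector db,
                              IntegerMatrix sm, std::string alphabet,
                              int word, double xdrop) {
  int cmap[256];
  std::fill(cmap, cmap + 256, -1);
  for (size_t i = 0; i < alphabet.size(); ++i)
    cmap[(unsigned char)alphabet[i]] = (int)i;
  const int MINSCORE = -4;
  auto pscore = [&](char a, char b) -> int {
    int ia = cmap[(unsigned char)a], ib = cmap[(unsigned char)b];
    if (ia < 0 || ib < 0) return MINSCORE;
    return sm(ia, ib);
  };

  const int nd = db.size();
  std::vector<std::string> ds(nd);
  for (int i = 0; i < nd; ++i) ds[i] = CHAR(STRING_ELT(db, i));

  // word index on raw characters
  std::unordered_map<uint32_t, std::vector<uint64_t>> idx;
  if (word != 4) stop("word must be 4");
  for (int d = 0; d < nd; ++d) {
    const std::string& s = ds[d];
    for (int p = 0; p + word <= (int)s.size(); ++p) {
      uint32_t code;
      std::memcpy(&code, s.c_str() + p, 4);
      idx[code].push_back(((uint64_t)d << 32) | (uint64_t)p);
    }
  }

  std::vector<int> o_q, o_d, o_sc, o_qs, o_qe, o_ss, o_se;
  const int nq = queries.size();
  for (int qi = 0; qi < nq; ++qi) {
    std::string q = CHAR(STRING_ELT(queries, qi));
    int ql = (int)q.size();
    if (ql < word) continue;
    std::unordered_map<uint64_t, int> diag_done;  // (db,diag) -> q scanned end
    std::unordered_map<int, Hsp> best;
    for (int qp = 0; qp + word <= ql; ++qp) {
      uint32_t code;
      std::memcpy(&code, q.c_str() + qp, 4);
      auto it = idx.find(code);
      if (it == idx.end()) continue;
      for (uint64_t h : it->second) {
        int d = (int)(h >> 32), sp = (int)(h & 0xFFFFFFFFULL);
        const std::string& s = ds[d];
        int sl = (int)s.size();
        int diag = sp - qp;
        uint64_t dk = ((uint64_t)d << 32) | (uint64_t)(uint32_t)(diag + (1 << 30));
        auto dd = diag_done.find(dk);
        if (dd != diag_done.end() && dd->second >= qp) continue;
        // seed score
        int cur = 0;
        for (int j = 0; j < word; ++j) cur += pscore(q[qp + j], s[sp + j]);
        int bestsc = cur, bqe = qp + word, bse = sp + word;
        // extend right
        {
          int i = qp + word, j = sp + word, c = cur;
          while (i < ql && j < sl) {
            c += pscore(q[i], s[j]);
            ++i; ++j;
            if (c > bestsc) { bestsc = c; bqe = i; bse = j; }
            else if (bestsc - c >= xdrop) break;
          }
          diag_done[dk] = i;  // skip future seeds already scanned on this diagonal
        }
        // extend left
        int bqs = qp, bss = sp;
        {
          int i = qp - 1, j = sp - 1, c = bestsc;
          int lbest = bestsc;
          while (i >= 0 && j >= 0) {
            c += pscore(q[i], s[j]);
            if (c > lbest) { lbest = c; bqs = i; bss = j; }
            else if (lbest - c >= xdrop) break;
            --i; --j;
          }
          bestsc = lbest;
        }
        Hsp& b = best[d];
        if (bestsc > b.score) {
          b.score = bestsc; b.qs = bqs; b.qe = bqe; b.ss = bss; b.se = bse;
        }
      }
    }
    for (auto& kv : best) {
      o_q.push_back(qi + 1); o_d.push_back(kv.first + 1);
      o_sc.push_back(kv.second.score);
      o_qs.push_back(kv.second.qs); o_qe.push_back(kv.second.qe);
      o_ss.push_back(kv.second.ss); o_se.push_back(kv.second.se);
    }
  }
  return DataFrame::create(_["query"] = wrap(o_q), _["db"] = wrap(o_d),
                           _["score"] = wrap(o_sc),
                           _["qstart"] = wrap(o_qs), _["qend"] = wrap(o_qe),
                           _["sstart"] = wrap(o_ss), _["send"] = wrap(o_se));
}

// ---------------------------------------------------------------------------
// ungapped nucleotide seed-and-extend local search (+1/-1), both strands
// ---------------------------------------------------------------------------

struct NtHsp {
  int score = INT_MIN;
  int strand = 1;
  int qs = 0, qe = 0, ss = 0, se = 0;
  int matches = 0;
};

// [[Rcpp::export]]
DataFrame rcpp_nt_search(CharacterVector queries, CharacterVector db,
                         int word, double xdrop) {
  const int nd = db.size();
  std::vector<std::string> ds(nd);
  for (int i = 0; i < nd; ++i) ds[i] = CHAR(STRING_ELT(db, i));
  if (word < 4 || word > 31) stop("word must be in [4, 31]");
  const uint64_t mask = (1ULL << (2 * word)) - 1;
  std::unordered_map<uint64_t, std::vector<uint64_t>> idx;
  for (int d = 0; d < nd; ++d) {
    const std::string& s = ds[d];
    uint64_t code = 0; int run = 0;
    for (int j = 0; j < (int)s.size(); ++j) {
      int b = base2bit(s[j]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run >= word)
        idx[code].push_back(((uint64_t)d << 32) | (uint64_t)(j - word + 1));
    }
  }

  std::vector<int> o_q, o_d, o_st, o_sc, o_m, o_len, o_qs, o_qe, o_ss, o_se;
  const int nq = queries.size();
  for (int qi = 0; qi < nq; ++qi) {
    std::string qf = CHAR(STRING_ELT(queries, qi));
    int ql = (int)qf.size();
    if (ql < word) continue;
    std::unordered_map<int, NtHsp> best;
    for (int strand = 0; strand < 2; ++strand) {
      std::string q = strand == 0 ? qf : revcomp_str(qf);
      std::unordered_map<uint64_t, int> diag_done;
      uint64_t code = 0; int run = 0;
      for (int j = 0; j < ql; ++j) {
        int b = base2bit(q[j]);
        if (b < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t)b) & mask;
        if (++run < word) continue;
        int qp = j - word + 1;
        auto it = idx.find(code);
        if (it == idx.end()) continue;
        for (uint64_t h : it->second) {
          int d = (int)(h >> 32), sp = (int)(h & 0xFFFFFFFFULL);
          const std::string& s = ds[d];
          int sl = (int)s.size();
          int diag = sp - qp;
          uint64_t dk = ((uint64_t)d << 32) | (uint64_t)(uint32_t)(diag + (1 << 30));
          auto dd = diag_done.find(dk);
          if (dd != diag_done.end() && dd->second >= qp) continue;
          int cur = word, bestsc = word;
          int bqe = qp + word, bse = sp + word;
          {
            int i = qp + word, jj = sp + word, c = cur;
            while (i < ql && jj < sl) {
              c += (q[i] == s[jj]) ? 1 : -1;
              ++i; ++jj;
              if (c > bestsc) { bestsc = c; bqe = i; bse = jj; }
              else if (bestsc - c >= xdrop) break;
            }
            diag_done[dk] = i;
          }
          int bqs = qp, bss = sp;
          {
            int i = qp - 1, jj = sp - 1, c = bestsc, lbest = bestsc;
            while (i >= 0 && jj >= 0) {
              c += (q[i] == s[jj]) ? 1 : -1;
              if (c > lbest) { lbest = c; bqs = i; bss = jj; }
              else if (lbest - c >= xdrop) break;
              --i; --jj;
            }
            bestsc = lbest;
          }
          NtHsp& bb = best[d];
          if (bestsc > bb.score) {
            int span = bqe - bqs;
            int matches = (span + bestsc) / 2;  // m - (span - m) = score
            int oqs = bqs, oqe = bqe;
            if (strand == 1) { oqs = ql - bqe; oqe = ql - bqs; }
            bb.score = bestsc; bb.strand = strand == 0 ? 1 : -1;
            bb.qs = oqs; bb.qe = oqe; bb.ss = bss; bb.se = bse;
            bb.matches = matches;
          }
        }
      }
    }
    for (auto& kv : best) {
      const NtHsp& b = kv.second;
      o_q.push_back(qi + 1); o_d.push_back(kv.first + 1);
      o_st.push_back(b.strand); o_sc.push_back(b.score);
      o_m.push_back(b.matches); o_len.push_back(b.qe - b.qs);
      o_qs.push_back(b.qs); o_qe.push_back(b.qe);
      o_ss.push_back(b.ss); o_se.push_back(b.se);
    }
  }
  return DataFrame::create(_["query"] = wrap(o_q), _["db"] = wrap(o_d),
                           _["strand"] = wrap(o_st), _["score"] = wrap(o_sc),
                           _["matches"] = wrap(o_m), _["span"] = wrap(o_len),
                           _["qstart"] = wrap(o_qs), _["qend"] = wrap(o_qe),
                           _["sstart"] = wrap(o_ss), _["send"] = wrap(o_se));
}

// ---------------------------------------------------------------------------
// exact seed hits of queries against a single genome sequence
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame rcpp_genome_seeds(CharacterVector queries, std::string genome, int word) {
  if (word < 8 || word > 31) stop("word must be in [8, 31]");
  const uint64_t mask = (1ULL << (2 * word)) - 1;
  std::vector<std::pair<uint64_t, uint32_t>> gidx;
  {
    uint64_t code = 0; int run = 0;
    for (int j = 0; j < (int)genome.size(); ++j) {
      int b = base2bit(genome[j]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run >= word) gidx.emplace_back(code, (uint32_t)(j - word + 1));
    }
    std::sort(gidx.begin(), gidx.end());
  }
  std::vector<int> o_q, o_qp, o_gp, o_st;
  const int nq = queries.size();
  for (int qi = 0; qi < nq; ++qi) {
    std::string qf = CHAR(STRING_ELT(queries, qi));
    for (int strand = 0; strand < 2; ++strand) {
      std::string q = strand == 0 ? qf : revcomp_str(qf);
      uint64_t code = 0; int run = 0;
      for (int j = 0; j < (int)q.size(); ++j) {
        int b = base2bit(q[j]);
        if (b < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t)b) & mask;
        if (++run < word) continue;
        int qp = j - word + 1;
        auto lo = std::lower_bound(gidx.begin(), gidx.end(),
                                   std::make_pair(code, (uint32_t)0));
        for (auto it = lo; it != gidx.end() && it->first == code; ++it) {
          o_q.push_back(qi + 1); o_qp.push_back(qp);
          o_gp.push_back((int)it->second);
          o_st.push_back(strand == 0 ? 1 : -1);
        }
      }
    }
  }
  return DataFrame::create(_["query"] = wrap(o_q), _["qpos"] = wrap(o_qp),
                           _["gpos"] = wrap(o_gp), _["strand"] = wrap(o_st));
}

// [[Rcpp::export]]
CharacterVector rcpp_revcomp(CharacterVector seqs) {
  const R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = revcomp_str(std::string(CHAR(STRING_ELT(seqs, i))));
  return out;
}

// count mismatches between equal-length strings (utility for tests/truth checks)
// [[Rcpp::export]]
IntegerVector rcpp_hamming(CharacterVector a, CharacterVector b) {
  if (a.size() != b.size()) stop("length mismatch");
  IntegerVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    const char* x = CHAR(STRING_ELT(a, i));
    const char* y = CHAR(STRING_ELT(b, i));
    size_t lx = std::strlen(x), ly = std::strlen(y);
    if (lx != ly) { out[i] = NA_INTEGER; continue; }
    int mm = 0;
    for (size_t j = 0; j < lx; ++j) if (x[j] != y[j]) ++mm;
    out[i] = mm;
  }
  return out;
}
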