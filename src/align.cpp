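// Protein alignment kernels: affine-gap Smith-Waterman (local) and
// Needleman-Wunsch (global identity), full-matrix for single pairs and
// banded (seed-and-extend) for the batch search and clustering paths. The
// k-mer index is open-addressing with positional postings so candidate
// pairs carry their seed diagonals. Substitution matrix and alphabet are
// supplied from R (Biostrings BLOSUM62); nothing is hard-coded here.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <cstring>
#include <climits>
#include <cctype>

using namespace Rcpp;

namespace {

const int NEG = INT_MIN / 4;

struct AlnStats {
  int score = 0, matches = 0, mismatches = 0, gapopens = 0, aln_len = 0;
  int qstart = 0, qend = 0, sstart = 0, send = 0;  // 1-based, 0 = empty
};

std::vector<int> make_code_map(const std::string& alphabet) {
  std::vector<int> code(256, -1);
  int xcode = (int)alphabet.size() - 1;
  for (size_t i = 0; i < alphabet.size(); ++i) {
    if (alphabet[i] == 'X') xcode = (int)i;
  }
  for (int c = 0; c < 256; ++c) code[c] = xcode;
  for (size_t i = 0; i < alphabet.size(); ++i) {
    code[(unsigned char)alphabet[i]] = (int)i;
    code[(unsigned char)std::tolower(alphabet[i])] = (int)i;
  }
  return code;
}

std::vector<int> encode(const char* s, const std::vector<int>& code) {
  size_t n = std::strlen(s);
  std::vector<int> v(n);
  for (size_t i = 0; i < n; ++i) v[i] = code[(unsigned char)s[i]];
  return v;
}

inline uint64_t kmer_key(const int* v, int k, int nA) {
  uint64_t key = 0;
  for (int t = 0; t < k; ++t) key = key * (uint64_t)nA + (uint64_t)v[t];
  return key;
}

inline uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// Open-addressing k-mer index with chained positional postings
// (reference id, position).
struct KmerIndex {
  std::vector<uint64_t> keys;
  std::vector<int32_t> slot_head;   // per hash slot: first posting or -1
  std::vector<uint8_t> used;
  std::vector<int32_t> nxt, ref, pos;
  uint64_t mask = 0;

  void build(const std::vector<std::vector<int>>& seqs, int k, int nA) {
    size_t total = 0;
    for (const auto& s : seqs) {
      if ((int)s.size() >= k) total += s.size() - k + 1;
    }
    size_t cap = 16;
    while (cap < 2 * total + 16) cap <<= 1;
    keys.assign(cap, 0);
    slot_head.assign(cap, -1);
    used.assign(cap, 0);
    mask = cap - 1;
    nxt.reserve(total); ref.reserve(total); pos.reserve(total);
    for (size_t r = 0; r < seqs.size(); ++r) add(seqs[r], (int32_t)r, k, nA);
  }

  void add(const std::vector<int>& s, int32_t r, int k, int nA) {
    if ((int)s.size() < k) return;
    for (size_t p = 0; p + k <= s.size(); ++p) {
      uint64_t key = kmer_key(s.data() + p, k, nA);
      size_t slot = mix64(key) & mask;
      while (used[slot] && keys[slot] != key) slot = (slot + 1) & mask;
      if (!used[slot]) { used[slot] = 1; keys[slot] = key; }
      int32_t id = (int32_t)ref.size();
      ref.push_back(r);
      pos.push_back((int32_t)p);
      nxt.push_back(slot_head[slot]);
      slot_head[slot] = id;
    }
  }

  int32_t find(uint64_t key) const {
    if (mask == 0) return -1;
    size_t slot = mix64(key) & mask;
    while (used[slot]) {
      if (keys[slot] == key) return slot_head[slot];
      slot = (slot + 1) & mask;
    }
    return -1;
  }
};

// ---------- full-matrix kernels (single-pair oracle paths) ----------

AlnStats sw_align_full(const std::vector<int>& q, const std::vector<int>& s,
                       const int* sub, int nA, int gap_open, int gap_ext) {
  int m = (int)q.size(), n = (int)s.size();
  AlnStats st;
  if (m == 0 || n == 0) return st;
  std::vector<int> H(n + 1, 0), Fc(n + 1, NEG);
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int Hdiag = H[0];
    int Erow = NEG;
    const int* srow = sub + (size_t)q[i - 1] * nA;
    uint8_t* tbrow = &tb[(size_t)i * (n + 1)];
    for (int j = 1; j <= n; ++j) {
      int eopen = H[j - 1] - gap_open - gap_ext;
      int eext = Erow - gap_ext;
      uint8_t b = 0;
      if (eext > eopen) { Erow = eext; b |= 4; } else Erow = eopen;
      int fopen = H[j] - gap_open - gap_ext;
      int fext = Fc[j] - gap_ext;
      if (fext > fopen) { Fc[j] = fext; b |= 8; } else Fc[j] = fopen;
      int diag = Hdiag + srow[s[j - 1]];
      int h = 0; uint8_t hb = 0;
      if (diag > h) { h = diag; hb = 1; }
      if (Fc[j] > h) { h = Fc[j]; hb = 2; }
      if (Erow > h) { h = Erow; hb = 3; }
      Hdiag = H[j];
      H[j] = h;
      tbrow[j] = b | hb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0) return st;
  st.score = best; st.qend = bi; st.send = bj;
  int i = bi, j = bj, state = 0;
  while (true) {
    uint8_t b = tb[(size_t)i * (n + 1) + j];
    if (state == 0) {
      uint8_t hb = b & 3;
      if (hb == 0) break;
      if (hb == 1) {
        ++st.aln_len;
        if (q[i - 1] == s[j - 1]) ++st.matches; else ++st.mismatches;
        --i; --j;
      } else if (hb == 2) state = 2;
      else state = 1;
    } else if (state == 2) {
      ++st.aln_len;
      bool ext = (b & 8) != 0;
      --i;
      if (!ext) { ++st.gapopens; state = 0; }
    } else {
      ++st.aln_len;
      bool ext = (b & 4) != 0;
      --j;
      if (!ext) { ++st.gapopens; state = 0; }
    }
  }
  st.qstart = i + 1; st.sstart = j + 1;
  return st;
}

void nw_identity_full(const std::vector<int>& q, const std::vector<int>& s,
                      int match, int mismatch, int gap_open, int gap_ext,
                      int* out_matches, int* out_columns, int* out_score) {
  int m = (int)q.size(), n = (int)s.size();
  if (m == 0 || n == 0) {
    *out_matches = 0; *out_columns = std::max(m, n); *out_score = 0;
    return;
  }
  std::vector<int> H(n + 1), Fc(n + 1, NEG);
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  H[0] = 0;
  for (int j = 1; j <= n; ++j) {
    H[j] = -gap_open - j * gap_ext;
    tb[j] = 3 | 4;
  }
  for (int i = 1; i <= m; ++i) {
    int Hdiag = H[0];
    H[0] = -gap_open - i * gap_ext;
    int Erow = NEG;
    uint8_t* tbrow = &tb[(size_t)i * (n + 1)];
    tbrow[0] = 2 | 8;
    for (int j = 1; j <= n; ++j) {
      int eopen = H[j - 1] - gap_open - gap_ext;
      int eext = Erow - gap_ext;
      uint8_t b = 0;
      if (eext > eopen) { Erow = eext; b |= 4; } else Erow = eopen;
      int fopen = H[j] - gap_open - gap_ext;
      int fext = Fc[j] - gap_ext;
      if (fext > fopen) { Fc[j] = fext; b |= 8; } else Fc[j] = fopen;
      int diag = Hdiag + (q[i - 1] == s[j - 1] ? match : mismatch);
      int h = diag; uint8_t hb = 1;
      if (Fc[j] > h) { h = Fc[j]; hb = 2; }
      if (Erow > h) { h = Erow; hb = 3; }
      Hdiag = H[j];
      H[j] = h;
      tbrow[j] = b | hb;
    }
  }
  int i = m, j = n, state = 0, matches = 0, columns = 0;
  while (i > 0 || j > 0) {
    uint8_t b = tb[(size_t)i * (n + 1) + j];
    if (state == 0) {
      uint8_t hb = b & 3;
      if (i == 0) hb = 3;
      if (j == 0) hb = 2;
      if (hb == 1) {
        ++columns;
        if (q[i - 1] == s[j - 1]) ++matches;
        --i; --j;
      } else if (hb == 2) state = 2;
      else state = 1;
    } else if (state == 2) {
      ++columns;
      bool ext = (b & 8) != 0;
      --i;
      if (!ext || i == 0) state = 0;
    } else {
      ++columns;
      bool ext = (b & 4) != 0;
      --j;
      if (!ext || j == 0) state = 0;
    }
  }
  *out_matches = matches; *out_columns = columns; *out_score = H[n];
}

// ---------- banded kernels ----------
// Diagonals d = j - i; the band [dlo, dhi] is indexed b = j - i - dlo.
// Workspace is reused across calls.

struct BandWork {
  std::vector<int> Hp, Hc, Fp, Fc;
  std::vector<uint8_t> tb;
};

// banded local alignment; band must be within [1-m, n-1]
AlnStats sw_align_banded(const std::vector<int>& q, const std::vector<int>& s,
                         const int* sub, int nA, int gap_open, int gap_ext,
                         int dlo, int dhi, BandWork& w) {
  int m = (int)q.size(), n = (int)s.size();
  AlnStats st;
  if (m == 0 || n == 0) return st;
  dlo = std::max(dlo, 1 - m);
  dhi = std::min(dhi, n - 1);
  if (dlo > dhi) return st;
  int wd = dhi - dlo + 1;
  w.Hp.assign(wd + 1, 0);       // +1 sentinel for b+1 access
  w.Fp.assign(wd + 1, NEG);
  w.Hc.assign(wd + 1, 0);
  w.Fc.assign(wd + 1, NEG);
  w.tb.assign((size_t)(m + 1) * wd, 0);
  int best = 0, bi = 0, bb = 0;
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(1, i + dlo);
    int jhi = std::min(n, i + dhi);
    if (jlo > jhi) {  // band entirely off the subject for this row
      for (int b = 0; b < wd; ++b) { w.Hc[b] = 0; w.Fc[b] = NEG; }
      std::swap(w.Hp, w.Hc);
      std::swap(w.Fp, w.Fc);
      continue;
    }
    int blo = jlo - i - dlo, bhi = jhi - i - dlo;  // 0 <= blo <= bhi < wd
    uint8_t* tbrow = &w.tb[(size_t)i * wd];
    const int* srow = sub + (size_t)q[i - 1] * nA;
    int Erow = NEG;
    // cells outside [blo, bhi] in this row are outside the band
    for (int b = 0; b < blo; ++b) { w.Hc[b] = 0; w.Fc[b] = NEG; }
    for (int b = bhi + 1; b < wd; ++b) { w.Hc[b] = 0; w.Fc[b] = NEG; }
    for (int b = blo; b <= bhi; ++b) {
      int j = i + dlo + b;
      int eopen = (b > blo) ? w.Hc[b - 1] - gap_open - gap_ext : NEG;
      int eext = Erow - gap_ext;
      uint8_t tbb = 0;
      if (eext > eopen) { Erow = eext; tbb |= 4; } else Erow = eopen;
      // up: (i-1, j) has band index b+1 (sentinel NEG/0 handled by assign)
      int hup = (b + 1 < wd) ? w.Hp[b + 1] : 0;
      int fup = (b + 1 < wd) ? w.Fp[b + 1] : NEG;
      int fopen = hup - gap_open - gap_ext;
      int fext = fup - gap_ext;
      int f;
      if (fext > fopen) { f = fext; tbb |= 8; } else f = fopen;
      w.Fc[b] = f;
      int diag = w.Hp[b] + srow[s[j - 1]];
      int h = 0; uint8_t hb = 0;
      if (diag > h) { h = diag; hb = 1; }
      if (f > h) { h = f; hb = 2; }
      if (Erow > h) { h = Erow; hb = 3; }
      w.Hc[b] = h;
      tbrow[b] = tbb | hb;
      if (h > best) { best = h; bi = i; bb = b; }
    }
    std::swap(w.Hp, w.Hc);
    std::swap(w.Fp, w.Fc);
  }
  if (best <= 0) return st;
  st.score = best;
  int i = bi, b = bb, state = 0;
  st.qend = bi; st.send = bi + dlo + bb;
  while (true) {
    uint8_t tbyte = w.tb[(size_t)i * wd + b];
    if (state == 0) {
      uint8_t hb = tbyte & 3;
      if (hb == 0) break;
      if (hb == 1) {
        int j = i + dlo + b;
        ++st.aln_len;
        if (q[i - 1] == s[j - 1]) ++st.matches; else ++st.mismatches;
        --i;  // b unchanged on diagonal moves
      } else if (hb == 2) state = 2;
      else state = 1;
    } else if (state == 2) {
      ++st.aln_len;
      bool ext = (tbyte & 8) != 0;
      --i; ++b;
      if (!ext) { ++st.gapopens; state = 0; }
    } else {
      ++st.aln_len;
      bool ext = (tbyte & 4) != 0;
      --b;
      if (!ext) { ++st.gapopens; state = 0; }
    }
  }
  st.qstart = i + 1; st.sstart = i + dlo + b + 1;
  return st;
}

// banded global alignment for identity; the band always contains
// diagonals 0 and n - m so both corners are reachable
void nw_identity_banded(const std::vector<int>& q, const std::vector<int>& s,
                        int match, int mismatch, int gap_open, int gap_ext,
                        int pad, BandWork& w,
                        int* out_matches, int* out_columns) {
  int m = (int)q.size(), n = (int)s.size();
  if (m == 0 || n == 0) {
    *out_matches = 0; *out_columns = std::max(m, n);
    return;
  }
  int dlo = std::min(0, n - m) - pad;
  int dhi = std::max(0, n - m) + pad;
  dlo = std::max(dlo, -m);
  dhi = std::min(dhi, n);
  int wd = dhi - dlo + 1;
  // row 0: j = d, for d in [max(dlo,0), dhi]
  w.Hp.assign(wd + 1, NEG);
  w.Fp.assign(wd + 1, NEG);
  w.Hc.assign(wd + 1, NEG);
  w.Fc.assign(wd + 1, NEG);
  w.tb.assign((size_t)(m + 1) * wd, 0);
  for (int b = 0; b < wd; ++b) {
    int j = dlo + b;
    if (j < 0 || j > std::min(n, dhi)) continue;
    w.Hp[b] = (j == 0) ? 0 : -gap_open - j * gap_ext;
  }
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(0, i + dlo);
    int jhi = std::min(n, i + dhi);
    int blo = jlo - i - dlo, bhi = jhi - i - dlo;
    uint8_t* tbrow = &w.tb[(size_t)i * wd];
    int Erow = NEG;
    for (int b = 0; b < wd; ++b) { w.Hc[b] = NEG; w.Fc[b] = NEG; }
    for (int b = blo; b <= bhi; ++b) {
      int j = i + dlo + b;
      if (j == 0) {
        w.Hc[b] = -gap_open - i * gap_ext;
        w.Fc[b] = w.Hc[b];
        tbrow[b] = 2 | 8;
        continue;
      }
      int eopen = (b > 0 && w.Hc[b - 1] > NEG / 2)
                      ? w.Hc[b - 1] - gap_open - gap_ext : NEG;
      int eext = Erow - gap_ext;
      uint8_t tbb = 0;
      if (eext > eopen) { Erow = eext; tbb |= 4; } else Erow = eopen;
      int hup = (b + 1 < wd) ? w.Hp[b + 1] : NEG;
      int fup = (b + 1 < wd) ? w.Fp[b + 1] : NEG;
      int fopen = (hup > NEG / 2) ? hup - gap_open - gap_ext : NEG;
      int fext = (fup > NEG / 2) ? fup - gap_ext : NEG;
      int f;
      if (fext > fopen) { f = fext; tbb |= 8; } else f = fopen;
      w.Fc[b] = f;
      int diag = (w.Hp[b] > NEG / 2)
                     ? w.Hp[b] + (q[i - 1] == s[j - 1] ? match : mismatch)
                     : NEG;
      int h = diag; uint8_t hb = 1;
      if (f > h) { h = f; hb = 2; }
      if (Erow > h) { h = Erow; hb = 3; }
      w.Hc[b] = h;
      tbrow[b] = tbb | hb;
    }
    std::swap(w.Hp, w.Hc);
    std::swap(w.Fp, w.Fc);
  }
  int i = m, b = n - m - dlo, state = 0, matches = 0, columns = 0;
  while (i > 0 || i + dlo + b > 0) {
    uint8_t tbyte = (i >= 1) ? w.tb[(size_t)i * wd + b] : 0;
    int j = i + dlo + b;
    if (state == 0) {
      uint8_t hb = tbyte & 3;
      if (i == 0) hb = 3;
      if (j == 0) hb = 2;
      if (hb == 1) {
        ++columns;
        if (q[i - 1] == s[j - 1]) ++matches;
        --i;
      } else if (hb == 2) state = 2;
      else state = 1;
    } else if (state == 2) {
      ++columns;
      bool ext = (tbyte & 8) != 0;
      --i; ++b;
      if (!ext || i == 0) state = 0;
    } else {
      ++columns;
      bool ext = (tbyte & 4) != 0;
      --b;
      if (!ext || i + dlo + b == 0) state = 0;
    }
  }
  *out_matches = matches; *out_columns = columns;
}

}  // namespace

// [[Rcpp::export]]
List cpp_local_align(std::string a, std::string b, IntegerMatrix sub,
                     std::string alphabet, int gap_open, int gap_ext) {
  std::vector<int> code = make_code_map(alphabet);
  std::vector<int> q = encode(a.c_str(), code), s = encode(b.c_str(), code);
  int nA = sub.nrow();
  AlnStats st = sw_align_full(q, s, sub.begin(), nA, gap_open, gap_ext);
  return List::create(
      _["score"] = st.score, _["matches"] = st.matches,
      _["mismatches"] = st.mismatches, _["gapopens"] = st.gapopens,
      _["length"] = st.aln_len, _["qstart"] = st.qstart, _["qend"] = st.qend,
      _["sstart"] = st.sstart, _["send"] = st.send);
}

// [[Rcpp::export]]
List cpp_global_identity(std::string a, std::string b, int match, int mismatch,
                         int gap_open, int gap_ext) {
  std::string alphabet = "ABCDEFGHIJKLMNOPQRSTUVWXYZ*";
  std::vector<int> code = make_code_map(alphabet);
  std::vector<int> q = encode(a.c_str(), code), s = encode(b.c_str(), code);
  int matches, columns, score;
  nw_identity_full(q, s, match, mismatch, gap_open, gap_ext, &matches,
                   &columns, &score);
  return List::create(_["matches"] = matches, _["columns"] = columns,
                      _["score"] = score);
}

// Batch local alignment of queries against references. Candidate pairs
// must have two seed k-mers on nearby diagonals (within two_hit_window;
// the classic two-hit rule, which suppresses chance single-k-mer
// collisions) unless two_hit_window < 0, in which case one seed suffices.
// Alignment is banded around the seed diagonals (+/- band_pad). Returns
// one row per retained pair with raw score >= min_score.
// [[Rcpp::export]]
DataFrame cpp_batch_search(CharacterVector queries, CharacterVector refs,
                           IntegerMatrix sub, std::string alphabet, int k,
                           double min_score, int gap_open, int gap_ext,
                           int two_hit_window = 2, int band_pad = 24) {
  std::vector<int> code = make_code_map(alphabet);
  int nA = sub.nrow();
  const int* subp = sub.begin();
  int n_q = queries.size();
  int n_refs = refs.size();

  std::vector<std::vector<int>> refv(n_refs);
  for (int r = 0; r < n_refs; ++r) {
    refv[r] = encode(CHAR(STRING_ELT(refs, r)), code);
  }
  KmerIndex index;
  index.build(refv, k, nA);

  const int DBITS = 21, DOFF = 1 << 20;
  std::vector<uint64_t> seeds;
  seeds.reserve(512);
  BandWork work;
  std::vector<int> out_q, out_r, out_score, out_match, out_mis, out_gap,
      out_len, out_qs, out_qe, out_ss, out_se;

  for (int qi = 0; qi < n_q; ++qi) {
    std::vector<int> qv = encode(CHAR(STRING_ELT(queries, qi)), code);
    int m = (int)qv.size();
    if (m < k) continue;
    seeds.clear();
    for (int p = 0; p + k <= m; ++p) {
      int32_t e = index.find(kmer_key(qv.data() + p, k, nA));
      for (; e >= 0; e = index.nxt[e]) {
        // diagonal d = subject pos - query pos (0-based)
        int d = index.pos[e] - p;
        seeds.push_back(((uint64_t)index.ref[e] << DBITS) |
                        (uint32_t)(d + DOFF));
      }
    }
    std::sort(seeds.begin(), seeds.end());
    size_t i = 0;
    while (i < seeds.size()) {
      int r = (int)(seeds[i] >> DBITS);
      size_t j = i;
      bool ok = two_hit_window < 0;
      int anchor = (int)(seeds[i] & ((1 << DBITS) - 1)) - DOFF;
      int dprev = INT_MIN / 2, dmin = INT_MAX, dmax = INT_MIN;
      while (j < seeds.size() && (int)(seeds[j] >> DBITS) == r) {
        int d = (int)(seeds[j] & ((1 << DBITS) - 1)) - DOFF;
        if (!ok && d - dprev <= two_hit_window) { ok = true; anchor = d; }
        dprev = d;
        if (d < dmin) dmin = d;
        if (d > dmax) dmax = d;
        ++j;
      }
      i = j;
      if (!ok) continue;
      // band across the seed diagonals, clamped around the anchor so one
      // stray collision cannot blow the band wide open
      int dlo = std::max(dmin, anchor - 64) - band_pad;
      int dhi = std::min(dmax, anchor + 64) + band_pad;
      AlnStats st = sw_align_banded(qv, refv[r], subp, nA, gap_open,
                                    gap_ext, dlo, dhi, work);
      if (st.score >= min_score) {
        out_q.push_back(qi + 1); out_r.push_back(r + 1);
        out_score.push_back(st.score); out_match.push_back(st.matches);
        out_mis.push_back(st.mismatches); out_gap.push_back(st.gapopens);
        out_len.push_back(st.aln_len); out_qs.push_back(st.qstart);
        out_qe.push_back(st.qend); out_ss.push_back(st.sstart);
        out_se.push_back(st.send);
      }
    }
    if ((qi & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  return DataFrame::create(
      _["query"] = out_q, _["ref"] = out_r, _["score"] = out_score,
      _["matches"] = out_match, _["mismatches"] = out_mis,
      _["gapopens"] = out_gap, _["length"] = out_len, _["qstart"] = out_qs,
      _["qend"] = out_qe, _["sstart"] = out_ss, _["send"] = out_se);
}

// Greedy clustering in the order given (caller sorts by decreasing
// length): each sequence joins the earliest-founded representative with
// banded global identity >= threshold among representatives sharing
// enough k-mers, else founds a new cluster. Returns the 1-based index of
// each sequence's representative.
// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double identity, int k,
                                 double min_share_frac, int match,
                                 int mismatch, int gap_open, int gap_ext,
                                 int band_pad = 32) {
  std::string alphabet = "ABCDEFGHIJKLMNOPQRSTUVWXYZ*";
  std::vector<int> code = make_code_map(alphabet);
  int nA = (int)alphabet.size();
  int n = seqs.size();
  IntegerVector assign(n);
  std::vector<std::vector<int>> sv(n);
  size_t total_kmers = 0;
  for (int i = 0; i < n; ++i) {
    sv[i] = encode(CHAR(STRING_ELT(seqs, i)), code);
    if ((int)sv[i].size() >= k) total_kmers += sv[i].size() - k + 1;
  }
  KmerIndex index;
  {
    // pre-size the table for the worst case (every sequence founds)
    size_t cap = 16;
    while (cap < 2 * total_kmers + 16) cap <<= 1;
    index.keys.assign(cap, 0);
    index.slot_head.assign(cap, -1);
    index.used.assign(cap, 0);
    index.mask = cap - 1;
  }
  std::vector<int> rep_of;  // founded rep id -> sequence index
  std::vector<int> counts, touched;
  BandWork work;

  for (int i = 0; i < n; ++i) {
    counts.resize(rep_of.size(), 0);
    std::vector<int> cand;
    int m = (int)sv[i].size();
    size_t nk = m >= k ? m - k + 1 : 0;
    if (nk == 0) {
      for (size_t t = 0; t < rep_of.size(); ++t) cand.push_back((int)t);
    } else {
      for (int p = 0; p + k <= m; ++p) {
        int32_t e = index.find(kmer_key(sv[i].data() + p, k, nA));
        for (; e >= 0; e = index.nxt[e]) {
          int r = index.ref[e];
          if (counts[r] == 0) touched.push_back(r);
          ++counts[r];
        }
      }
      int need = std::max(1, (int)std::ceil(min_share_frac * (double)nk));
      for (int r : touched) {
        if (counts[r] >= need) cand.push_back(r);
        counts[r] = 0;
      }
      touched.clear();
      std::sort(cand.begin(), cand.end());
    }
    int chosen = -1;
    for (int r : cand) {
      int matches, columns;
      nw_identity_banded(sv[i], sv[rep_of[r]], match, mismatch, gap_open,
                         gap_ext, band_pad, work, &matches, &columns);
      if (columns > 0 && (double)matches / (double)columns >= identity) {
        chosen = rep_of[r];
        break;
      }
    }
    if (chosen >= 0) {
      assign[i] = chosen + 1;
    } else {
      assign[i] = i + 1;
      index.add(sv[i], (int32_t)rep_of.size(), k, nA);
      rep_of.push_back(i);
    }
    if ((i & 0xFF) == 0) Rcpp::checkUserInterrupt();
  }
  return assign;
}
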