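// Internal sequence matcher: approximate motif scan (Myers bit-parallel),
// anchored-overlap banded affine alignment, and a k-mer seed index used to
// shortlist candidate flanks before alignment.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// ---------------------------------------------------------------------------
// Myers bit-parallel semi-global scan: all end positions where the pattern
// matches with <= max_edits, reduced to non-overlapping best-first hits.
// Pattern length must be <= 64.
// ---------------------------------------------------------------------------

// unit-cost DP anchored at the window end (pattern fully consumed, free
// start column) -> returns best start column within the window
static int anchored_start(const std::string& pat, const std::string& win,
                          int* out_dist) {
  const int m = (int)pat.size(), L = (int)win.size();
  std::vector<int> prev(L + 1), cur(L + 1);
  std::vector<int> oprev(L + 1), ocur(L + 1);
  for (int j = 0; j <= L; ++j) { prev[j] = 0; oprev[j] = j; }
  for (int i = 1; i <= m; ++i) {
    cur[0] = i; ocur[0] = 0;
    for (int j = 1; j <= L; ++j) {
      int diag = prev[j - 1] + (pat[i - 1] == win[j - 1] ? 0 : 1);
      int up = prev[j] + 1, left = cur[j - 1] + 1;
      int best = diag, orig = oprev[j - 1];
      if (up < best) { best = up; orig = oprev[j]; }
      if (left < best) { best = left; orig = ocur[j - 1]; }
      cur[j] = best; ocur[j] = orig;
    }
    std::swap(prev, cur); std::swap(oprev, ocur);
  }
  *out_dist = prev[L];
  return oprev[L];
}

// [[Rcpp::export]]
DataFrame cpp_motif_scan(std::string text, std::string pattern, int max_edits) {
  const int m = (int)pattern.size();
  if (m < 1 || m > 64) stop("pattern length must be in [1, 64]");
  const int n = (int)text.size();
  uint64_t Peq[4] = {0, 0, 0, 0};
  for (int i = 0; i < m; ++i) {
    int b = base2bits(pattern[i]);
    if (b >= 0) Peq[b] |= (1ULL << i);
  }
  uint64_t Pv = ~0ULL, Mv = 0;
  if (m < 64) Pv = (1ULL << m) - 1;
  const uint64_t high = 1ULL << (m - 1);
  int score = m;
  std::vector<std::pair<int, int>> cand; // (end inclusive, edits)
  for (int j = 0; j < n; ++j) {
    int b = base2bits(text[j]);
    uint64_t Eq = (b >= 0) ? Peq[b] : 0ULL;
    uint64_t Xv = Eq | Mv;
    uint64_t Xh = (((Eq & Pv) + Pv) ^ Pv) | Eq;
    uint64_t Ph = Mv | ~(Xh | Pv);
    uint64_t Mh = Pv & Xh;
    if (Ph & high) ++score; else if (Mh & high) --score;
    Ph <<= 1; // search variant: top DP row is all zeros
    Mh <<= 1;
    Pv = (Mh | ~(Xv | Ph));
    Mv = Ph & Xv;
    if (m < 64) { Pv &= (1ULL << m) - 1; Mv &= (1ULL << m) - 1; }
    if (score <= max_edits) cand.push_back(std::make_pair(j, score));
  }
  // keep local minima within runs, then greedy non-overlapping best-first
  std::vector<std::pair<int, int>> minima;
  for (size_t i = 0; i < cand.size(); ++i) {
    bool better_nb = false;
    if (i > 0 && cand[i - 1].first == cand[i].first - 1 &&
        cand[i - 1].second <= cand[i].second) better_nb = true;
    if (i + 1 < cand.size() && cand[i + 1].first == cand[i].first + 1 &&
        cand[i + 1].second < cand[i].second) better_nb = true;
    if (!better_nb) minima.push_back(cand[i]);
  }
  std::sort(minima.begin(), minima.end(),
            [](const std::pair<int,int>& a, const std::pair<int,int>& b) {
              if (a.second != b.second) return a.second < b.second;
              return a.first < b.first;
            });
  std::vector<int> acc_end, acc_start, acc_ed;
  for (size_t i = 0; i < minima.size(); ++i) {
    int end = minima[i].first;
    bool clash = false;
    for (size_t a = 0; a < acc_end.size(); ++a)
      if (std::abs(acc_end[a] - end) < m) { clash = true; break; }
    if (clash) continue;
    int w0 = std::max(0, end - m - max_edits + 1);
    std::string win = text.substr(w0, end - w0 + 1);
    int dist = 0;
    int sc = anchored_start(pattern, win, &dist);
    acc_end.push_back(end);
    acc_start.push_back(w0 + sc);
    acc_ed.push_back(dist);
  }
  // report in genomic order
  std::vector<int> ord(acc_end.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return acc_start[a] < acc_start[b]; });
  IntegerVector start(ord.size()), end(ord.size()), edits(ord.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    start[i] = acc_start[ord[i]];
    end[i] = acc_end[ord[i]] + 1; // 0-based half-open
    edits[i] = acc_ed[ord[i]];
  }
  return DataFrame::create(_["start"] = start, _["end"] = end,
                           _["edits"] = edits);
}

// ---------------------------------------------------------------------------
// Anchored-overlap banded affine alignment.
// Both sequences are anchored at their right ends; leading overhangs of
// either sequence are free. Scores: match/mismatch; gap of length g costs
// gap_open + (g - 1) * gap_ext. Returns per ref: score, ref bases covered,
// query bases covered. Used with reversed inputs for left-anchored cases.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_anchor_align(std::string query, CharacterVector refs,
                               int band, double match, double mismatch,
                               double gap_open, double gap_ext) {
  const int n = (int)query.size();
  const double NEG = -1e18;
  NumericMatrix out(refs.size(), 3);
  for (int r = 0; r < refs.size(); ++r) {
    std::string ref = as<std::string>(refs[r]);
    const int m = (int)ref.size();
    std::vector<double> Hp(m + 1), Hc(m + 1), Ep(m + 1), Ec(m + 1),
        Fp(m + 1), Fc(m + 1);
    // origin = start column (ref index) packed with start row
    std::vector<int> OHp(m + 1), OHc(m + 1), OEp(m + 1), OEc(m + 1),
        OFp(m + 1), OFc(m + 1);
    const int diag = m - n; // corner diagonal offset
    for (int j = 0; j <= m; ++j) {
      Hp[j] = 0.0; OHp[j] = (j << 12); // start row 0..4095 in low bits
      Ep[j] = NEG; Fp[j] = NEG; OEp[j] = OFp[j] = (j << 12);
    }
    for (int i = 1; i <= n; ++i) {
      int jlo = std::max(1, i + diag - band);
      int jhi = std::min(m, i + diag + band);
      for (int j = 0; j <= m; ++j) { Hc[j] = NEG; Ec[j] = NEG; Fc[j] = NEG; }
      Hc[0] = 0.0; OHc[0] = (0 << 12) | std::min(i, 4095);
      for (int j = jlo; j <= jhi; ++j) {
        // E: gap in query (consume ref)
        double eo = Hc[j - 1] + gap_open, ee = Ec[j - 1] + gap_ext;
        if (eo >= ee) { Ec[j] = eo; OEc[j] = OHc[j - 1]; }
        else { Ec[j] = ee; OEc[j] = OEc[j - 1]; }
        // F: gap in ref (consume query)
        double fo = Hp[j] + gap_open, fe = Fp[j] + gap_ext;
        if (fo >= fe) { Fc[j] = fo; OFc[j] = OHp[j]; }
        else { Fc[j] = fe; OFc[j] = OFp[j]; }
        char qc = query[i - 1], rc = ref[j - 1];
        double sub = (base2bits(qc) >= 0 && base2bits(qc) == base2bits(rc))
                         ? match : mismatch;
        double dg = Hp[j - 1] + sub;
        double best = dg; int orig = OHp[j - 1];
        if (Ec[j] > best) { best = Ec[j]; orig = OEc[j]; }
        if (Fc[j] > best) { best = Fc[j]; orig = OFc[j]; }
        Hc[j] = best; OHc[j] = orig;
      }
      std::swap(Hp, Hc); std::swap(Ep, Ec); std::swap(Fp, Fc);
      std::swap(OHp, OHc); std::swap(OEp, OEc); std::swap(OFp, OFc);
    }
    double score = Hp[m];
    int orig = OHp[m];
    int oj = orig >> 12, oi = orig & 0xFFF;
    out(r, 0) = (score <= NEG / 2) ? R_NegInf : score;
    out(r, 1) = m - oj;           // ref bases covered
    out(r, 2) = n - oi;           // query bases covered
  }
  return out;
}

// ---------------------------------------------------------------------------
// Seed index over candidate flank sequences.
// ---------------------------------------------------------------------------
struct SeedIndex {
  int k;
  int nrefs;
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> map;
};

// [[Rcpp::export]]
SEXP cpp_seed_index(CharacterVector refs, int k) {
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  SeedIndex* idx = new SeedIndex();
  idx->k = k;
  idx->nrefs = (int)refs.size();
  for (int r = 0; r < refs.size(); ++r) {
    std::string s = as<std::string>(refs[r]);
    uint64_t key = 0, mask = (1ULL << (2 * k)) - 1;
    int run = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k)
        idx->map[key].push_back(std::make_pair((int32_t)r, (int32_t)(i - k + 1)));
    }
  }
  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

// For each ref, the maximum diagonal-consistent seed count (diagonal bins of
// width 64, adjacent bins pooled).
// [[Rcpp::export]]
IntegerVector cpp_seed_hits(std::string query, SEXP index) {
  XPtr<SeedIndex> idx(index);
  const int k = idx->k;
  std::unordered_map<uint64_t, int32_t> bins;
  uint64_t key = 0, mask = (1ULL << (2 * k)) - 1;
  int run = 0;
  const int n = (int)query.size();
  for (int i = 0; i < n; ++i) {
    int b = base2bits(query[i]);
    if (b < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)b) & mask;
    if (++run < k) continue;
    auto it = idx->map.find(key);
    if (it == idx->map.end()) continue;
    const auto& v = it->second;
    if (v.size() > 16) continue; // repetitive seed, skip
    int qpos = i - k + 1;
    for (size_t h = 0; h < v.size(); ++h) {
      int64_t diag = (int64_t)qpos - v[h].second + (1 << 20);
      uint64_t bk = ((uint64_t)v[h].first << 32) | (uint64_t)(diag >> 6);
      bins[bk] += 1;
    }
  }
  IntegerVector out(idx->nrefs);
  for (auto& kv : bins) {
    int r = (int)(kv.first >> 32);
    uint64_t bin = kv.first & 0xFFFFFFFFULL;
    int tot = kv.second;
    auto nb = bins.find(((uint64_t)r << 32) | (bin + 1));
    if (nb != bins.end()) tot += nb->second;
    if (tot > out[r]) out[r] = tot;
  }
  return out;
}
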