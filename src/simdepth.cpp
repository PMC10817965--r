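// Simulation helpers (random DNA, i.i.d. read errors) and the k-mer
// window-depth engine used for flank copy-number estimation.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
using namespace Rcpp;

static inline int b2b(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}
static const char BASES[4] = {'A', 'C', 'G', 'T'};

static std::string revcomp_str(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[s.size() - 1 - i];
    switch (c) {
    case 'A': r[i] = 'T'; break; case 'C': r[i] = 'G'; break;
    case 'G': r[i] = 'C'; break; case 'T': r[i] = 'A'; break;
    default: r[i] = 'N';
    }
  }
  return r;
}

// [[Rcpp::export]]
std::string cpp_random_dna(int len, double gc) {
  RNGScope scope;
  std::string s(len, 'A');
  double pc = gc / 2.0, pa = (1.0 - gc) / 2.0;
  for (int i = 0; i < len; ++i) {
    double u = unif_rand();
    if (u < pa) s[i] = 'A';
    else if (u < 2 * pa) s[i] = 'T';
    else if (u < 2 * pa + pc) s[i] = 'C';
    else s[i] = 'G';
  }
  return s;
}

// i.i.d. per-base errors: deletion, insertion (before the base), substitution
// [[Rcpp::export]]
CharacterVector cpp_mutate_reads(CharacterVector seqs, double p_sub,
                                 double p_ins, double p_del) {
  RNGScope scope;
  CharacterVector out(seqs.size());
  for (int r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    std::string o;
    o.reserve(s.size() + 16);
    for (size_t i = 0; i < s.size(); ++i) {
      double u = unif_rand();
      if (u < p_del) continue;
      if (u < p_del + p_ins)
        o.push_back(BASES[(int)(unif_rand() * 4) & 3]);
      if (u < p_del + p_ins + p_sub) {
        int b = b2b(s[i]);
        int nb = (b < 0) ? ((int)(unif_rand() * 4) & 3)
                         : ((b + 1 + (int)(unif_rand() * 3)) & 3);
        o.push_back(BASES[nb]);
      } else {
        o.push_back(s[i]);
      }
    }
    out[r] = o;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Window depth: estimate, per reference window, the number of window bases
// covered by each read, split by a per-read flag (lox-containing or not).
// Matching is by globally unique k-mers; a read's covered interval within a
// window is the k-mer hit extent in its better-matching orientation (a read
// overlaps a window in one orientation except across an inversion breakpoint,
// where the dominant side wins).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_window_depth(CharacterVector windows, CharacterVector reads,
                      LogicalVector is_lox, int k, int min_hits) {
  if (k < 8 || k > 31) stop("k must be in [8, 31]");
  std::unordered_map<uint64_t, std::pair<int32_t, int32_t>> map;
  std::unordered_map<uint64_t, bool> dup;
  uint64_t mask = (1ULL << (2 * k)) - 1;
  for (int w = 0; w < windows.size(); ++w) {
    std::string s = as<std::string>(windows[w]);
    uint64_t key = 0; int run = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int b = b2b(s[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run < k) continue;
      if (map.count(key)) dup[key] = true;
      else map[key] = std::make_pair((int32_t)w, (int32_t)(i - k + 1));
    }
  }
  for (auto& kv : dup) map.erase(kv.first);

  const int W = (int)windows.size();
  NumericVector cov_lox(W), cov_nolox(W);
  std::vector<int> cnt[2], mn[2], mx[2];
  for (int o = 0; o < 2; ++o) {
    cnt[o].resize(W); mn[o].resize(W); mx[o].resize(W);
  }
  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    bool lox = is_lox[r];
    for (int ori = 0; ori < 2; ++ori) {
      const std::string s = ori == 0 ? fwd : revcomp_str(fwd);
      std::fill(cnt[ori].begin(), cnt[ori].end(), 0);
      std::fill(mn[ori].begin(), mn[ori].end(), 1 << 30);
      std::fill(mx[ori].begin(), mx[ori].end(), -1);
      uint64_t key = 0; int run = 0;
      for (int i = 0; i < (int)s.size(); ++i) {
        int b = b2b(s[i]);
        if (b < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)b) & mask;
        if (++run < k) continue;
        auto it = map.find(key);
        if (it == map.end()) continue;
        int w = it->second.first, p = it->second.second;
        cnt[ori][w]++;
        if (p < mn[ori][w]) mn[ori][w] = p;
        if (p > mx[ori][w]) mx[ori][w] = p;
      }
    }
    for (int w = 0; w < W; ++w) {
      int ori = (cnt[1][w] > cnt[0][w]) ? 1 : 0;
      if (cnt[ori][w] < min_hits) continue;
      double covered = (double)(mx[ori][w] - mn[ori][w] + k);
      if (lox) cov_lox[w] += covered; else cov_nolox[w] += covered;
    }
  }
  return List::create(_["covered_lox"] = cov_lox,
                      _["covered_nolox"] = cov_nolox);
}
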