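#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit encode A/C/G/T; returns -1 for anything else
static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Collect canonical k-mers (lexicographic min of forward / reverse complement,
// on the 2-bit encoding) of one sequence. k must be <= 32.
static void canonical_kmers(const char *s, int n, int k,
                            std::vector<uint64_t> &out) {
  out.clear();
  if (n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | (((uint64_t)(3 - b)) << (2 * (k - 1)));
    if (++valid >= k) out.push_back(fwd < rev ? fwd : rev);
  }
}

static int median_count(const std::vector<uint64_t> &kmers,
                        std::unordered_map<uint64_t, int> &tab) {
  std::vector<int> cnt;
  cnt.reserve(kmers.size());
  for (uint64_t km : kmers) {
    auto it = tab.find(km);
    cnt.push_back(it == tab.end() ? 0 : it->second);
  }
  size_t m = cnt.size() / 2;
  std::nth_element(cnt.begin(), cnt.begin() + m, cnt.end());
  int hi = cnt[m];
  if (cnt.size() % 2 == 1) return hi;
  std::nth_element(cnt.begin(), cnt.begin() + m - 1, cnt.end());
  // median of even-sized set: lower of the rounded pair (integer floor of mean)
  return (hi + cnt[m - 1]) / 2;
}

static void add_kmers(const std::vector<uint64_t> &kmers,
                      std::unordered_map<uint64_t, int> &tab) {
  for (uint64_t km : kmers) ++tab[km];
}

// [[Rcpp::export(name = ".dgn_keep_single")]]
LogicalVector dgn_keep_single(CharacterVector reads, int k, int cutoff) {
  int n = reads.size();
  LogicalVector keep(n);
  std::unordered_map<uint64_t, int> tab;
  std::vector<uint64_t> kms;
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(reads, i));
    canonical_kmers(s, LENGTH(STRING_ELT(reads, i)), k, kms);
    bool kp = kms.empty() || median_count(kms, tab) < cutoff;
    keep[i] = kp;
    if (kp) add_kmers(kms, tab);
  }
  return keep;
}

// Paired streaming rule: keep the pair if EITHER mate's median k-mer
// abundance is below the cutoff; kept pairs feed both mates into the counter.
// [[Rcpp::export(name = ".dgn_keep_pairs")]]
LogicalVector dgn_keep_pairs(CharacterVector mate1, CharacterVector mate2,
                             int k, int cutoff) {
  int n = mate1.size();
  if (mate2.size() != n) stop("mate vectors differ in length");
  LogicalVector keep(n);
  std::unordered_map<uint64_t, int> tab;
  std::vector<uint64_t> k1, k2;
  for (int i = 0; i < n; ++i) {
    canonical_kmers(CHAR(STRING_ELT(mate1, i)), LENGTH(STRING_ELT(mate1, i)), k, k1);
    canonical_kmers(CHAR(STRING_ELT(mate2, i)), LENGTH(STRING_ELT(mate2, i)), k, k2);
    bool below1 = k1.empty() || median_count(k1, tab) < cutoff;
    bool below2 = k2.empty() || median_count(k2, tab) < cutoff;
    bool kp = below1 || below2;
    keep[i] = kp;
    if (kp) { add_kmers(k1, tab); add_kmers(k2, tab); }
  }
  return keep;
}

// Longest contiguous run of bases with phred strictly greater than min_phred.
// Returns an n x 2 matrix: 1-based start and length (0 if no qualifying base).
// Ties broken by the leftmost run.
// [[Rcpp::export(name = ".hq_runs")]]
IntegerMatrix hq_runs(CharacterVector qual, int min_phred, int offset) {
  int n = qual.size();
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    const char *q = CHAR(STRING_ELT(qual, i));
    int len = LENGTH(STRING_ELT(qual, i));
    int best_start = 0, best_len = 0, cur_start = 0, cur_len = 0;
    for (int j = 0; j < len; ++j) {
      if ((int)q[j] - offset > min_phred) {
        if (cur_len == 0) cur_start = j;
        ++cur_len;
        if (cur_len > best_len) { best_len = cur_len; best_start = cur_start; }
      } else {
        cur_len = 0;
      }
    }
    out(i, 0) = best_len > 0 ? best_start + 1 : 0;
    out(i, 1) = best_len;
  }
  return out;
}

// Smith-Waterman local alignment of string pairs (linear gap penalty).
// Returns an n x 3 matrix: best score, matched bases on the best path,
// alignment columns (incl. gaps). Intended for short reads vs database
// windows; quadratic DP with explicit traceback.
// [[Rcpp::export(name = ".sw_local")]]
NumericMatrix sw_local(CharacterVector a, CharacterVector b,
                       double match, double mismatch, double gap) {
  int n = a.size();
  if (b.size() != n) stop("length mismatch");
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    const char *x = CHAR(STRING_ELT(a, i));
    const char *y = CHAR(STRING_ELT(b, i));
    int la = LENGTH(STRING_ELT(a, i)), lb = LENGTH(STRING_ELT(b, i));
    std::vector<double> H((la + 1) * (lb + 1), 0.0);
    std::vector<unsigned char> tb((la + 1) * (lb + 1), 0); // 1 diag 2 up 3 left
    double best = 0.0; int bi = 0, bj = 0;
    for (int r = 1; r <= la; ++r) {
      for (int c = 1; c <= lb; ++c) {
        double diag = H[(r - 1) * (lb + 1) + c - 1] +
          (x[r - 1] == y[c - 1] ? match : mismatch);
        double up = H[(r - 1) * (lb + 1) + c] + gap;
        double left = H[r * (lb + 1) + c - 1] + gap;
        double v = diag; unsigned char t = 1;
        if (up > v) { v = up; t = 2; }
        if (left > v) { v = left; t = 3; }
        if (v <= 0) { v = 0; t = 0; }
        H[r * (lb + 1) + c] = v;
        tb[r * (lb + 1) + c] = t;
        if (v > best) { best = v; bi = r; bj = c; }
      }
    }
    int matches = 0, cols = 0, r = bi, c = bj;
    while (r > 0 && c > 0 && tb[r * (lb + 1) + c] != 0) {
      unsigned char t = tb[r * (lb + 1) + c];
      ++cols;
      if (t == 1) { if (x[r - 1] == y[c - 1]) ++matches; --r; --c; }
      else if (t == 2) { --r; }
      else { --c; }
    }
    out(i, 0) = best; out(i, 1) = matches; out(i, 2) = cols;
  }
  return out;
}

// Elementwise Hamming distance between equal-length strings; -1 on length
// mismatch (caller treats as non-aligning).
// [[Rcpp::export(name = ".hamming")]]
IntegerVector hamming(CharacterVector a, CharacterVector b) {
  int n = a.size();
  if (b.size() != n) stop("length mismatch");
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *x = CHAR(STRING_ELT(a, i));
    const char *y = CHAR(STRING_ELT(b, i));
    int la = LENGTH(STRING_ELT(a, i)), lb = LENGTH(STRING_ELT(b, i));
    if (la != lb) { out[i] = -1; continue; }
    int d = 0;
    for (int j = 0; j < la; ++j) if (x[j] != y[j]) ++d;
    out[i] = d;
  }
  return out;
}
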