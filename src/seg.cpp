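#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
using namespace Rcpp;

// 21-letter internal alphabet: the 20 standard residues plus X.
// Sequences are validated / normalized on the R side before they get here.
static const char* AA = "ACDEFGHIKLMNPQRSTVWYX";
static const int NAA = 21;

static inline int aa_index(char c) {
  switch (c) {
    case 'A': return 0;  case 'C': return 1;  case 'D': return 2;
    case 'E': return 3;  case 'F': return 4;  case 'G': return 5;
    case 'H': return 6;  case 'I': return 7;  case 'K': return 8;
    case 'L': return 9;  case 'M': return 10; case 'N': return 11;
    case 'P': return 12; case 'Q': return 13; case 'R': return 14;
    case 'S': return 15; case 'T': return 16; case 'V': return 17;
    case 'W': return 18; case 'Y': return 19; case 'X': return 20;
    default:  return -1;
  }
}

static inline double entropy_bits(const int* cnt, int total) {
  double h = 0.0;
  for (int i = 0; i < NAA; ++i) {
    if (cnt[i] > 0) {
      double p = (double)cnt[i] / (double)total;
      h -= p * std::log2(p);
    }
  }
  return h;
}

static std::vector<int> encode(const std::string& seq) {
  std::vector<int> v(seq.size());
  for (size_t i = 0; i < seq.size(); ++i) {
    int k = aa_index(seq[i]);
    if (k < 0) stop("illegal residue '%c' at position %d", seq[i], (int)(i + 1));
    v[i] = k;
  }
  return v;
}

// Shannon entropy (bits) of every length-W window; result[p] is the window
// starting at 1-based position p+1.
// [[Rcpp::export(name = ".seg_window_entropies")]]
NumericVector seg_window_entropies(std::string seq, int W) {
  int L = (int)seq.size();
  if (W < 2) stop("W must be >= 2");
  if (L < W) return NumericVector(0);
  std::vector<int> v = encode(seq);
  NumericVector out(L - W + 1);
  int cnt[NAA];
  std::memset(cnt, 0, sizeof(cnt));
  for (int i = 0; i < W; ++i) cnt[v[i]]++;
  out[0] = entropy_bits(cnt, W);
  for (int p = 1; p <= L - W; ++p) {
    cnt[v[p - 1]]--;
    cnt[v[p + W - 1]]++;
    out[p] = entropy_bits(cnt, W);
  }
  return out;
}

struct Reg { int a, b; };  // 0-based inclusive residue interval

// Minimum-probability refinement: over all contiguous subintervals [i, j] of
// [a, b], minimize len * (H(sub) - log2(omega)) — the Stirling surrogate of
// the log-probability of the subinterval's composition under an equiprobable
// omega-letter null. Ties: longer subinterval, then smaller start.
static Reg refine_region(const std::vector<int>& v, int a, int b, double omega) {
  const double c = std::log2(omega);
  const double eps = 1e-9;
  int m = b - a + 1;
  // A region of a single residue type is its own optimum; also guards the
  // O(m^2) scan against pathologically long uniform tracts.
  {
    bool mono = true;
    for (int i = a + 1; i <= b; ++i) if (v[i] != v[a]) { mono = false; break; }
    if (mono || m > 5000) return Reg{a, b};
  }
  double best = R_PosInf;
  int bestI = a, bestJ = a;
  int cnt[NAA];
  for (int i = a; i <= b; ++i) {
    std::memset(cnt, 0, sizeof(cnt));
    double lh = 0.0;  // running L * H in bits: L*log2(L) - sum n*log2(n)
    double sumn = 0.0;
    for (int j = i; j <= b; ++j) {
      int k = v[j];
      if (cnt[k] > 0) sumn -= cnt[k] * std::log2((double)cnt[k]);
      cnt[k]++;
      sumn += cnt[k] * std::log2((double)cnt[k]);
      int len = j - i + 1;
      lh = len * std::log2((double)len) - sumn;
      double score = lh - len * c;
      if (score < best - eps ||
          (score < best + eps &&
           (len > bestJ - bestI + 1 ||
            (len == bestJ - bestI + 1 && i < bestI)))) {
        best = score; bestI = i; bestJ = j;
      }
    }
  }
  return Reg{bestI, bestJ};
}

// Full segmentation: trigger (H <= K1), extension (H <= K2) runs, merging of
// overlapping/adjoining residue regions, optional refinement.
// Returns a 2-column integer matrix of 1-based inclusive intervals.
// [[Rcpp::export(name = ".seg_segment")]]
IntegerMatrix seg_segment(std::string seq, int W, double K1, double K2,
                          bool refine, double alphabet_size) {
  int L = (int)seq.size();
  std::vector<Reg> merged;
  if (L >= W && W >= 2) {
    std::vector<int> v = encode(seq);
    int nw = L - W + 1;
    std::vector<double> H(nw);
    {
      int cnt[NAA];
      std::memset(cnt, 0, sizeof(cnt));
      for (int i = 0; i < W; ++i) cnt[v[i]]++;
      H[0] = entropy_bits(cnt, W);
      for (int p = 1; p < nw; ++p) {
        cnt[v[p - 1]]--;
        cnt[v[p + W - 1]]++;
        H[p] = entropy_bits(cnt, W);
      }
    }
    // maximal runs of extension-eligible window starts that contain a trigger
    std::vector<Reg> regs;
    int p = 0;
    while (p < nw) {
      if (H[p] <= K2) {
        int q = p;
        bool trig = false;
        while (q < nw && H[q] <= K2) { if (H[q] <= K1) trig = true; ++q; }
        if (trig) regs.push_back(Reg{p, q - 1 + W - 1});  // residues covered
        p = q;
      } else ++p;
    }
    for (size_t i = 0; i < regs.size(); ++i) {
      if (!merged.empty() && regs[i].a <= merged.back().b + 1)
        merged.back().b = std::max(merged.back().b, regs[i].b);
      else
        merged.push_back(regs[i]);
    }
    if (refine) {
      for (size_t i = 0; i < merged.size(); ++i)
        merged[i] = refine_region(v, merged[i].a, merged[i].b, alphabet_size);
    }
  }
  IntegerMatrix out((int)merged.size(), 2);
  for (size_t i = 0; i < merged.size(); ++i) {
    out(i, 0) = merged[i].a + 1;
    out(i, 1) = merged[i].b + 1;
  }
  colnames(out) = CharacterVector::create("start", "end");
  return out;
}
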