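#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Banded Needleman-Wunsch on nucleotide strings, linear gap penalty.
// Returns alignment column count and matched column count of an optimal
// global alignment restricted to diagonals within `band` of the corner-to-
// corner diagonal (the band is widened by the length difference so the
// global path always fits). Scores use two rolling rows; the byte-sized
// traceback matrix is kept to recover the counts. Used to close short
// inter-anchor gaps during ANI chaining.
// [[Rcpp::export(name = ".banded_global_stats")]]
List banded_global_stats(std::string x, std::string y, int band = 50,
                         double match = 1.0, double mismatch = -1.0,
                         double gap = -2.0) {
  const int n = (int)x.size(), m = (int)y.size();
  if (n == 0 || m == 0) {
    return List::create(_["columns"] = n + m, _["matches"] = 0);
  }
  int dlo = std::min(0, m - n) - band;
  int dhi = std::max(0, m - n) + band;
  const double NEG = -std::numeric_limits<double>::infinity();
  const int W = m + 1;
  std::vector<double> Sp(W, NEG), Sc(W, NEG);
  std::vector<signed char> T((size_t)(n + 1) * W, 0); // 1 diag, 2 up, 3 left
  // row 0
  Sp[0] = 0.0;
  {
    int jmax = std::min(m, dhi);
    for (int j = 1; j <= jmax; ++j) {
      Sp[j] = Sp[j - 1] + gap;
      T[j] = 3;
    }
  }
  for (int i = 1; i <= n; ++i) {
    std::fill(Sc.begin(), Sc.end(), NEG);
    int jmin = std::max(0, i + dlo), jmax = std::min(m, i + dhi);
    for (int j = jmin; j <= jmax; ++j) {
      double best = NEG; signed char tb = 0;
      if (j > 0 && Sp[j - 1] > NEG) {
        double sc = Sp[j - 1] +
          (x[i - 1] == y[j - 1] && x[i - 1] != 'N' ? match : mismatch);
        if (sc > best) { best = sc; tb = 1; }
      }
      if (Sp[j] > NEG) {
        double sc = Sp[j] + gap;
        if (sc > best) { best = sc; tb = 2; }
      }
      if (j > 0 && Sc[j - 1] > NEG) {
        double sc = Sc[j - 1] + gap;
        if (sc > best) { best = sc; tb = 3; }
      }
      Sc[j] = best;
      T[(size_t)i * W + j] = tb;
    }
    std::swap(Sp, Sc);
  }
  if (Sp[m] == NEG) {
    return List::create(_["columns"] = n + m, _["matches"] = 0);
  }
  int i = n, j = m, columns = 0, matches = 0;
  while (i > 0 || j > 0) {
    signed char tb = T[(size_t)i * W + j];
    if (tb == 1) {
      ++columns;
      if (x[i - 1] == y[j - 1] && x[i - 1] != 'N') ++matches;
      --i; --j;
    } else if (tb == 2) { ++columns; --i; }
    else if (tb == 3) { ++columns; --j; }
    else break; // outside band (cannot happen for a reachable cell)
  }
  return List::create(_["columns"] = columns, _["matches"] = matches);
}

// Hamming distance between equal-length windows of two raw byte vectors.
// starts are 1-based; any byte pair differing counts 1.
// [[Rcpp::export(name = ".hamming_windows")]]
IntegerVector hamming_windows(RawVector subject, IntegerVector starts,
                              RawVector query) {
  const int L = query.size();
  const int n = subject.size();
  IntegerVector out(starts.size());
  for (int c = 0; c < starts.size(); ++c) {
    int s = starts[c] - 1;
    if (s < 0 || s + L > n) { out[c] = NA_INTEGER; continue; }
    int mm = 0;
    for (int t = 0; t < L; ++t) if (subject[s + t] != query[t]) ++mm;
    out[c] = mm;
  }
  return out;
}
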