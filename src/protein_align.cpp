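#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Global affine-gap (Gotoh) protein alignment of one query against many
// references, returning per-reference identity (identical columns /
// alignment columns) and residue-paired coverage of each sequence.
// Counts (matches, paired residues, columns) are packed into one 64-bit
// word and propagated along an optimal path with deterministic
// tie-breaking (diagonal > vertical > horizontal). Scoring: substitution
// matrix + gap of length k costing open + k * ext (the pairwiseAlignment
// convention).

static const double NEG = -1e18;

static inline int64_t pack(int64_t match, int64_t paired, int64_t cols) {
  return (match << 42) | (paired << 21) | cols;
}
static const int64_t ONE_MATCH = ((int64_t)1 << 42) | ((int64_t)1 << 21) | 1;
static const int64_t ONE_PAIR = ((int64_t)1 << 21) | 1;
static const int64_t ONE_COL = 1;

// [[Rcpp::export(name = ".protein_align_many")]]
NumericMatrix protein_align_many(std::string query,
                                 std::vector<std::string> refs,
                                 NumericMatrix submat,
                                 double open = 11.0, double ext = 1.0) {
  const int m = (int)query.size();
  NumericMatrix out(refs.size(), 4);
  colnames(out) = CharacterVector::create("identity", "cov_ref",
                                          "cov_query", "score");
  std::vector<int> q(m);
  for (int j = 0; j < m; ++j) {
    int c = query[j] - 'A';
    q[j] = (c < 0 || c > 25) ? 23 : c; // unknown letters score as X
  }
  std::vector<double> sM(m + 1), sX(m + 1), sY(m + 1),
    pM(m + 1), pX(m + 1), pY(m + 1);
  std::vector<int64_t> cM(m + 1), cX(m + 1), cY(m + 1),
    dM(m + 1), dX(m + 1), dY(m + 1);
  for (size_t r = 0; r < refs.size(); ++r) {
    const std::string &a = refs[r];
    const int n = (int)a.size();
    // previous row (p*/d*), current row (s*/c*)
    pM[0] = 0.0; pX[0] = pY[0] = NEG;
    dM[0] = dX[0] = dY[0] = 0;
    for (int j = 1; j <= m; ++j) {
      pM[j] = pX[j] = NEG;
      pY[j] = -(open + ext * j);
      dM[j] = dX[j] = 0;
      dY[j] = pack(0, 0, j);
    }
    for (int i = 1; i <= n; ++i) {
      int ac = a[i - 1] - 'A';
      if (ac < 0 || ac > 25) ac = 23;
      sM[0] = sY[0] = NEG;
      sX[0] = -(open + ext * i);
      cM[0] = cY[0] = 0;
      cX[0] = pack(0, 0, i);
      for (int j = 1; j <= m; ++j) {
        double sub = submat(ac, q[j - 1]);
        int64_t inc = (a[i - 1] == query[j - 1]) ? ONE_MATCH : ONE_PAIR;
        // M from best of previous-row diagonal cells (M > X > Y on ties)
        double bs = pM[j - 1]; int64_t bc = dM[j - 1];
        if (pX[j - 1] > bs) { bs = pX[j - 1]; bc = dX[j - 1]; }
        if (pY[j - 1] > bs) { bs = pY[j - 1]; bc = dY[j - 1]; }
        sM[j] = bs + sub; cM[j] = bc + inc;
        // X: gap in query (vertical)
        if (pM[j] - open - ext >= pX[j] - ext) {
          sX[j] = pM[j] - open - ext; cX[j] = dM[j] + ONE_COL;
        } else {
          sX[j] = pX[j] - ext; cX[j] = dX[j] + ONE_COL;
        }
        // Y: gap in ref (horizontal)
        if (sM[j - 1] - open - ext >= sY[j - 1] - ext) {
          sY[j] = sM[j - 1] - open - ext; cY[j] = cM[j - 1] + ONE_COL;
        } else {
          sY[j] = sY[j - 1] - ext; cY[j] = cY[j - 1] + ONE_COL;
        }
      }
      std::swap(sM, pM); std::swap(sX, pX); std::swap(sY, pY);
      std::swap(cM, dM); std::swap(cX, dX); std::swap(cY, dY);
    }
    double bs = pM[m]; int64_t bc = dM[m];
    if (pX[m] > bs) { bs = pX[m]; bc = dX[m]; }
    if (pY[m] > bs) { bs = pY[m]; bc = dY[m]; }
    int64_t match = bc >> 42;
    int64_t paired = (bc >> 21) & 0x1FFFFF;
    int64_t cols = bc & 0x1FFFFF;
    out(r, 0) = cols > 0 ? (double)match / cols : 0.0;
    out(r, 1) = n > 0 ? (double)paired / n : 0.0;
    out(r, 2) = m > 0 ? (double)paired / m : 0.0;
    out(r, 3) = bs;
  }
  return out;
}
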