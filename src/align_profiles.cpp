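// Affine-gap (Gotoh) global profile-profile alignment used by the
// progressive multiple aligner.  Profiles are 5 x n frequency matrices over
// (A, C, G, T, -); columns sum to 1.  Column-column score is the expected
// substitution score over the base frequencies; pre-existing gap characters
// contribute nothing (their penalty was paid when introduced).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline double colscore(const NumericMatrix& A, const NumericMatrix& B,
                              int i, int j, double match, double mismatch) {
  double s = 0.0;
  for (int a = 0; a < 4; ++a) {
    double fa = A(a, i);
    if (fa == 0.0) continue;
    for (int b = 0; b < 4; ++b) {
      double fb = B(b, j);
      if (fb == 0.0) continue;
      s += fa * fb * (a == b ? match : mismatch);
    }
  }
  return s;
}

// [[Rcpp::export(name = ".align_profiles_cpp")]]
IntegerVector align_profiles_cpp(NumericMatrix profA, NumericMatrix profB,
                                 double match, double mismatch,
                                 double gap_open, double gap_ext) {
  const int n = profA.ncol(), m = profB.ncol();
  const double NEG = -1e30;
  std::vector<double> M((n + 1) * (m + 1), NEG), X(M), Y(M);
  std::vector<unsigned char> tM(M.size()), tX(M.size()), tY(M.size());
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = gap_open + gap_ext * (i - 1);
    tX[at(i, 0)] = (i == 1) ? 0 : 1;  // 0: came from M, 1: extended X
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = gap_open + gap_ext * (j - 1);
    tY[at(0, j)] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double sc = colscore(profA, profB, i - 1, j - 1, match, mismatch);
      // M: diagonal
      double bm = M[at(i - 1, j - 1)], bx = X[at(i - 1, j - 1)],
             by = Y[at(i - 1, j - 1)];
      unsigned char t = 0; double best = bm;
      if (bx > best) { best = bx; t = 1; }
      if (by > best) { best = by; t = 2; }
      M[at(i, j)] = best + sc; tM[at(i, j)] = t;
      // X: consume column of A (gap column added to B)
      double xo = M[at(i - 1, j)] + gap_open, xe = X[at(i - 1, j)] + gap_ext;
      if (xo >= xe) { X[at(i, j)] = xo; tX[at(i, j)] = 0; }
      else          { X[at(i, j)] = xe; tX[at(i, j)] = 1; }
      // Y: consume column of B
      double yo = M[at(i, j - 1)] + gap_open, ye = Y[at(i, j - 1)] + gap_ext;
      if (yo >= ye) { Y[at(i, j)] = yo; tY[at(i, j)] = 0; }
      else          { Y[at(i, j)] = ye; tY[at(i, j)] = 2; }
    }
  }

  // traceback from the best of the three end states (ties: M, then X, then Y)
  int i = n, j = m, state = 0;
  double best = M[at(n, m)];
  if (X[at(n, m)] > best) { best = X[at(n, m)]; state = 1; }
  if (Y[at(n, m)] > best) { state = 2; }
  std::vector<int> ops;  // 0 = both, 1 = A only (gap in B), 2 = B only
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0) { state = 2; continue; }
      if (j == 0) { state = 1; continue; }
      ops.push_back(0); state = tM[at(i, j)]; --i; --j;
    } else if (state == 1) {
      ops.push_back(1); state = tX[at(i, j)]; --i;
    } else {
      ops.push_back(2); state = tY[at(i, j)]; --j;
    }
  }
  return IntegerVector(ops.rbegin(), ops.rend());
}
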