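#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment of two profiles with affine
// gaps. Profiles are 6 x L frequency matrices over {A,C,G,T,N,-}; N and gap
// frequencies score 0 against anything. A gap of length k costs
// gap_open + gap_ext * (k - 1). Ties prefer the diagonal, then the
// up-move (gap in the second profile), for determinism.
//
// Returns a 2 x n_columns integer matrix of 1-based column indices into
// each profile, 0 marking a gap.

static inline double col_score(const NumericMatrix& A, const NumericMatrix& B,
                               int i, int j, double match, double mismatch) {
  double dot = 0.0, sa = 0.0, sb = 0.0;
  for (int a = 0; a < 4; ++a) {
    dot += A(a, i) * B(a, j);
    sa += A(a, i);
    sb += B(a, j);
  }
  return (match - mismatch) * dot + mismatch * sa * sb;
}

// [[Rcpp::export(name = ".gotoh_align")]]
IntegerMatrix gotoh_align(NumericMatrix A, NumericMatrix B,
                          double match, double mismatch,
                          double gap_open, double gap_ext) {
  const int n = A.ncol(), m = B.ncol();
  const double NEG = -1e30;

  // rolling score rows for states M (diag), E (gap in A: move in B),
  // F (gap in B: move in A)
  std::vector<double> Mprev(m + 1), Eprev(m + 1), Fprev(m + 1);
  std::vector<double> Mcur(m + 1), Ecur(m + 1), Fcur(m + 1);
  // traceback: 0 = from M, 1 = from E, 2 = from F
  std::vector<unsigned char> tbM((n + 1) * (size_t)(m + 1));
  std::vector<unsigned char> tbE((n + 1) * (size_t)(m + 1));
  std::vector<unsigned char> tbF((n + 1) * (size_t)(m + 1));
  const size_t row = m + 1;

  Mprev[0] = 0.0; Eprev[0] = NEG; Fprev[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = NEG;
    Eprev[j] = gap_open + gap_ext * (j - 1);
    Fprev[j] = NEG;
    tbE[j] = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    Mcur[0] = NEG;
    Ecur[0] = NEG;
    Fcur[0] = gap_open + gap_ext * (i - 1);
    tbF[i * row] = (i == 1) ? 0 : 2;
    for (int j = 1; j <= m; ++j) {
      double s = col_score(A, B, i - 1, j - 1, match, mismatch);
      // M: diagonal from best of previous states (prefer M, then F, then E)
      double bm = Mprev[j - 1]; unsigned char tm = 0;
      if (Fprev[j - 1] > bm) { bm = Fprev[j - 1]; tm = 2; }
      if (Eprev[j - 1] > bm) { bm = Eprev[j - 1]; tm = 1; }
      Mcur[j] = bm + s; tbM[i * row + j] = tm;
      // E: gap in A, consume B column j (move left)
      double eo = Mcur[j - 1] + gap_open;
      double ee = Ecur[j - 1] + gap_ext;
      if (eo >= ee) { Ecur[j] = eo; tbE[i * row + j] = 0; }
      else          { Ecur[j] = ee; tbE[i * row + j] = 1; }
      // F: gap in B, consume A column i (move up)
      double fo = Mprev[j] + gap_open;
      double fe = Fprev[j] + gap_ext;
      if (fo >= fe) { Fcur[j] = fo; tbF[i * row + j] = 0; }
      else          { Fcur[j] = fe; tbF[i * row + j] = 2; }
    }
    std::swap(Mprev, Mcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }

  // best terminal state (prefer M, then F, then E)
  double best = Mprev[m]; int state = 0;
  if (Fprev[m] > best) { best = Fprev[m]; state = 2; }
  if (Eprev[m] > best) { best = Eprev[m]; state = 1; }

  std::vector<int> pa, pb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) { state = (i == 0) ? 1 : 2; continue; }
      unsigned char t = tbM[(size_t)i * row + j];
      pa.push_back(i); pb.push_back(j);
      --i; --j; state = t;
    } else if (state == 1) {           // gap in A
      unsigned char t = tbE[(size_t)i * row + j];
      pa.push_back(0); pb.push_back(j);
      --j; state = (t == 1) ? 1 : 0;
    } else {                           // gap in B
      unsigned char t = tbF[(size_t)i * row + j];
      pa.push_back(i); pb.push_back(0);
      --i; state = (t == 2) ? 2 : 0;
    }
  }
  const int L = pa.size();
  IntegerMatrix path(2, L);
  for (int c = 0; c < L; ++c) {
    path(0, c) = pa[L - 1 - c];
    path(1, c) = pb[L - 1 - c];
  }
  path.attr("score") = best;
  return path;
}
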