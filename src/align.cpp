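#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap alignment kernels over a precomputed position-pair score
// matrix S (rows = positions of a, cols = positions of b).  Working on S
// rather than on sequences lets the same kernels serve residue-level
// alignment (S from a substitution matrix) and profile-profile alignment
// (S from column log-odds scores).
//
// Gap cost convention (BLAST-like): a gap of length L costs
// gap_open + L * gap_extend.

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List local_align_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double first_gap = gap_open + gap_extend;

  // DP matrices: M ends in an aligned pair, E in a gap in a (consumes b),
  // F in a gap in b (consumes a).
  std::vector<double> M((n + 1) * (m + 1), 0.0), E((n + 1) * (m + 1), NEG_INF),
      F((n + 1) * (m + 1), NEG_INF);
  std::vector<signed char> tM((n + 1) * (m + 1), 0), tE((n + 1) * (m + 1), 0),
      tF((n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // E: gap in a
      double eo = M[at(i, j - 1)] - first_gap;
      double ee = E[at(i, j - 1)] - gap_extend;
      if (eo >= ee) { E[at(i, j)] = eo; tE[at(i, j)] = 1; }
      else          { E[at(i, j)] = ee; tE[at(i, j)] = 2; }
      // F: gap in b
      double fo = M[at(i - 1, j)] - first_gap;
      double fe = F[at(i - 1, j)] - gap_extend;
      if (fo >= fe) { F[at(i, j)] = fo; tF[at(i, j)] = 1; }
      else          { F[at(i, j)] = fe; tF[at(i, j)] = 2; }
      // M: aligned pair ending at (i, j); tb 0 = fresh local start
      double dM = M[at(i - 1, j - 1)], dE = E[at(i - 1, j - 1)],
             dF = F[at(i - 1, j - 1)];
      double prev = 0.0;
      signed char tb = 0;
      if (dM > prev) { prev = dM; tb = 1; }
      if (dE > prev) { prev = dE; tb = 2; }
      if (dF > prev) { prev = dF; tb = 3; }
      M[at(i, j)] = prev + S(i - 1, j - 1);
      tM[at(i, j)] = tb;
      if (M[at(i, j)] > best) { best = M[at(i, j)]; bi = i; bj = j; }
    }
  }

  std::vector<int> pa, pb;
  if (best > 0.0) {
    int i = bi, j = bj, state = 0;  // 0 = M, 1 = E, 2 = F
    while (i > 0 && j > 0) {
      if (state == 0) {
        signed char tb = tM[at(i, j)];
        pa.push_back(i);
        pb.push_back(j);
        --i; --j;
        if (tb == 0) break;
        if (tb == 2) state = 1;
        else if (tb == 3) state = 2;
      } else if (state == 1) {
        signed char tb = tE[at(i, j)];
        --j;
        if (tb == 1) state = 0;
      } else {
        signed char tb = tF[at(i, j)];
        --i;
        if (tb == 1) state = 0;
      }
    }
    std::reverse(pa.begin(), pa.end());
    std::reverse(pb.begin(), pb.end());
  }
  return List::create(_["score"] = best,
                      _["pairs_a"] = wrap(pa),
                      _["pairs_b"] = wrap(pb));
}

// Global (Needleman-Wunsch) affine alignment; returns the aligned index
// vectors with 0 marking a gap.  Used by the center-star MSA merge.
// [[Rcpp::export]]
List global_align_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double first_gap = gap_open + gap_extend;
  std::vector<double> M((n + 1) * (m + 1), NEG_INF), E((n + 1) * (m + 1), NEG_INF),
      F((n + 1) * (m + 1), NEG_INF);
  std::vector<signed char> tM((n + 1) * (m + 1), 0), tE((n + 1) * (m + 1), 0),
      tF((n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) {
    E[at(0, j)] = -first_gap - (j - 1) * gap_extend;
    tE[at(0, j)] = (j == 1) ? 1 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    F[at(i, 0)] = -first_gap - (i - 1) * gap_extend;
    tF[at(i, 0)] = (i == 1) ? 1 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double eo = M[at(i, j - 1)] - first_gap, ee = E[at(i, j - 1)] - gap_extend,
             ef = F[at(i, j - 1)] - first_gap;
      E[at(i, j)] = eo; tE[at(i, j)] = 1;
      if (ee > E[at(i, j)]) { E[at(i, j)] = ee; tE[at(i, j)] = 2; }
      if (ef > E[at(i, j)]) { E[at(i, j)] = ef; tE[at(i, j)] = 3; }
      double fo = M[at(i - 1, j)] - first_gap, fe = F[at(i - 1, j)] - gap_extend,
             fE = E[at(i - 1, j)] - first_gap;
      F[at(i, j)] = fo; tF[at(i, j)] = 1;
      if (fe > F[at(i, j)]) { F[at(i, j)] = fe; tF[at(i, j)] = 2; }
      if (fE > F[at(i, j)]) { F[at(i, j)] = fE; tF[at(i, j)] = 3; }
      double dM = M[at(i - 1, j - 1)], dE = E[at(i - 1, j - 1)],
             dF = F[at(i - 1, j - 1)];
      double prev = dM; signed char tb = 1;
      if (dE > prev) { prev = dE; tb = 2; }
      if (dF > prev) { prev = dF; tb = 3; }
      M[at(i, j)] = prev + S(i - 1, j - 1);
      tM[at(i, j)] = tb;
    }
  }
  double sM = M[at(n, m)], sE = E[at(n, m)], sF = F[at(n, m)];
  int state = 0; double best = sM;
  if (sE > best) { best = sE; state = 1; }
  if (sF > best) { best = sF; state = 2; }

  std::vector<int> ga, gb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char tb = tM[at(i, j)];
      ga.push_back(i); gb.push_back(j);
      --i; --j;
      if (tb == 2) state = 1; else if (tb == 3) state = 2;
    } else if (state == 1) {
      signed char tb = tE[at(i, j)];
      ga.push_back(0); gb.push_back(j);
      --j;
      if (tb == 1) state = 0; else if (tb == 3) state = 2;
    } else {
      signed char tb = tF[at(i, j)];
      ga.push_back(i); gb.push_back(0);
      --i;
      if (tb == 1) state = 0; else if (tb == 3) state = 1;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["score"] = best,
                      _["gapped_a"] = wrap(ga),
                      _["gapped_b"] = wrap(gb));
}
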