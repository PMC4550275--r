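#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment of two profiles (Needleman-Wunsch / Gotoh).
//
// profA, profB: L x A residue-frequency matrices (one row per alignment
// column, one column per alphabet symbol; gap mass simply missing so a gap
// scores 0 against anything). sub: A x A substitution matrix. A gap run of
// length L costs gap_open + L * gap_extend. With free_end = true, gaps before
// the first or after the last column of either profile are free.
//
// Traceback is deterministic: at every cell the preferred predecessor order
// is match (diagonal) > gap-in-B (up, consumes A) > gap-in-A (left).
//
// Returns list(score, path) with path moves 0 = diagonal, 1 = up, 2 = left,
// ordered from the start of the alignment.
// [[Rcpp::export(name = ".align_profiles_cpp")]]
List align_profiles_cpp(NumericMatrix profA, NumericMatrix profB,
                        NumericMatrix sub, double gap_open,
                        double gap_extend, bool free_end) {
  const int L1 = profA.nrow(), L2 = profB.nrow(), A = sub.nrow();
  const double NEG = -1e300;

  // column-vs-column scores: S = (profA * sub) * t(profB)
  NumericMatrix S(L1, L2);
  {
    std::vector<double> M1((size_t)L1 * A, 0.0);
    for (int i = 0; i < L1; ++i)
      for (int b = 0; b < A; ++b) {
        double acc = 0.0;
        for (int a = 0; a < A; ++a) acc += profA(i, a) * sub(a, b);
        M1[(size_t)i * A + b] = acc;
      }
    for (int i = 0; i < L1; ++i)
      for (int j = 0; j < L2; ++j) {
        double acc = 0.0;
        for (int b = 0; b < A; ++b) acc += M1[(size_t)i * A + b] * profB(j, b);
        S(i, j) = acc;
      }
  }

  const int n1 = L1 + 1, n2 = L2 + 1;
  std::vector<double> M((size_t)n1 * n2, NEG), X((size_t)n1 * n2, NEG),
      Y((size_t)n1 * n2, NEG);
  // predecessor state per cell/state: 0 = M, 1 = X, 2 = Y
  std::vector<signed char> pm((size_t)n1 * n2, -1), px((size_t)n1 * n2, -1),
      py((size_t)n1 * n2, -1);
  auto at = [n2](int i, int j) { return (size_t)i * n2 + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i < n1; ++i) { // leading gaps in B (consume A)
    double go = free_end ? 0.0 : gap_open, ge = free_end ? 0.0 : gap_extend;
    X[at(i, 0)] = (i == 1 ? M[at(0, 0)] - go - ge : X[at(i - 1, 0)] - ge);
    px[at(i, 0)] = (i == 1 ? 0 : 1);
  }
  for (int j = 1; j < n2; ++j) { // leading gaps in A (consume B)
    double go = free_end ? 0.0 : gap_open, ge = free_end ? 0.0 : gap_extend;
    Y[at(0, j)] = (j == 1 ? M[at(0, 0)] - go - ge : Y[at(0, j - 1)] - ge);
    py[at(0, j)] = (j == 1 ? 0 : 2);
  }

  for (int i = 1; i < n1; ++i) {
    for (int j = 1; j < n2; ++j) {
      // diagonal
      double m0 = M[at(i - 1, j - 1)], x0 = X[at(i - 1, j - 1)],
             y0 = Y[at(i - 1, j - 1)];
      signed char st = 0;
      double best = m0;
      if (x0 > best) { best = x0; st = 1; }
      if (y0 > best) { best = y0; st = 2; }
      M[at(i, j)] = best + S(i - 1, j - 1);
      pm[at(i, j)] = st;
      // gap in B at column boundary j: free only when B exhausted/unstarted
      {
        bool fe = free_end && (j == L2);
        double go = fe ? 0.0 : gap_open, ge = fe ? 0.0 : gap_extend;
        double open_m = M[at(i - 1, j)] - go - ge;
        double open_y = Y[at(i - 1, j)] - go - ge;
        double ext = X[at(i - 1, j)] - ge;
        signed char stx = 0;
        double bx = open_m;
        if (ext > bx) { bx = ext; stx = 1; }
        if (open_y > bx) { bx = open_y; stx = 2; }
        X[at(i, j)] = bx;
        px[at(i, j)] = stx;
      }
      // gap in A
      {
        bool fe = free_end && (i == L1);
        double go = fe ? 0.0 : gap_open, ge = fe ? 0.0 : gap_extend;
        double open_m = M[at(i, j - 1)] - go - ge;
        double open_x = X[at(i, j - 1)] - go - ge;
        double ext = Y[at(i, j - 1)] - ge;
        signed char sty = 0;
        double by = open_m;
        if (open_x > by) { by = open_x; sty = 1; }
        if (ext > by) { by = ext; sty = 2; }
        Y[at(i, j)] = by;
        py[at(i, j)] = sty;
      }
    }
  }

  signed char st = 0;
  double score = M[at(L1, L2)];
  if (X[at(L1, L2)] > score) { score = X[at(L1, L2)]; st = 1; }
  if (Y[at(L1, L2)] > score) { score = Y[at(L1, L2)]; st = 2; }

  std::vector<int> path;
  int i = L1, j = L2;
  while (i > 0 || j > 0) {
    if (st == 0) {
      path.push_back(0);
      signed char prev = pm[at(i, j)];
      --i; --j;
      st = prev;
    } else if (st == 1) {
      path.push_back(1);
      signed char prev = px[at(i, j)];
      --i;
      st = prev;
    } else {
      path.push_back(2);
      signed char prev = py[at(i, j)];
      --j;
      st = prev;
    }
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["score"] = score, _["path"] = wrap(path));
}
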