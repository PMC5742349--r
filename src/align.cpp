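#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap (Gotoh) alignment over a precomputed column-vs-column
// score matrix S (rows = columns of profile A, cols = columns of profile B).
// A gap of length k costs open + k * extend; terminal gaps are charged.
// Returns the optimal score and a traceback path encoded as
// 1 = consume a column of both profiles, 2 = A only (gap in B),
// 3 = B only (gap in A).
// [[Rcpp::export]]
List gotoh_profile_align(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // tb*(i, j) = state (1=M, 2=X, 3=Y) the optimum came from
  IntegerMatrix tbM(n + 1, m + 1), tbX(n + 1, m + 1), tbY(n + 1, m + 1);

  M(0, 0) = 0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -(gap_open + i * gap_extend);
    tbX(i, 0) = (i == 1) ? 1 : 2;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -(gap_open + j * gap_extend);
    tbY(0, j) = (j == 1) ? 1 : 3;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double best = M(i - 1, j - 1); int src = 1;
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); src = 2; }
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); src = 3; }
      M(i, j) = best + S(i - 1, j - 1);
      tbM(i, j) = src;

      double xo = M(i - 1, j) - gap_open - gap_extend; int xs = 1;
      double cand = Y(i - 1, j) - gap_open - gap_extend;
      if (cand > xo) { xo = cand; xs = 3; }
      cand = X(i - 1, j) - gap_extend;
      if (cand >= xo) { xo = cand; xs = 2; }
      X(i, j) = xo; tbX(i, j) = xs;

      double yo = M(i, j - 1) - gap_open - gap_extend; int ys = 1;
      cand = X(i, j - 1) - gap_open - gap_extend;
      if (cand > yo) { yo = cand; ys = 2; }
      cand = Y(i, j - 1) - gap_extend;
      if (cand >= yo) { yo = cand; ys = 3; }
      Y(i, j) = yo; tbY(i, j) = ys;
    }
  }
  double score = M(n, m); int state = 1;
  if (X(n, m) > score) { score = X(n, m); state = 2; }
  if (Y(n, m) > score) { score = Y(n, m); state = 3; }

  std::vector<int> path;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int prev;
    if (state == 1) {
      prev = tbM(i, j); path.push_back(1); --i; --j;
    } else if (state == 2) {
      prev = tbX(i, j); path.push_back(2); --i;
    } else {
      prev = tbY(i, j); path.push_back(3); --j;
    }
    state = prev;
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["score"] = score,
                      _["path"] = IntegerVector(path.begin(), path.end()));
}
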