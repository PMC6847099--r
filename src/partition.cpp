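#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// McCaskill-style inside-outside computation over nested RNA secondary
// structures with a pair-weight-only energy model.
//
// A structure is a set of non-crossing pairs; pair (i,j) is allowed when
// its weight w(i,j) > 0 and j - i > minh (at least minh unpaired bases
// enclosed).  A structure's weight is the product of its pair weights; the
// empty structure has weight 1.
//
// Inside:  Z(i,j) = Z(i,j-1) + sum_k Z(i,k-1) * w(k,j) * Z(k+1,j-1)
// Outside: W(i,j) = Z(1,i-1)*Z(j+1,n)
//                   + sum over the innermost enclosing pair (k,l):
//                     w(k,l) * W(k,l) * Z(k+1,i-1) * Z(j+1,l-1)
// rewritten with G(k,j) = sum_l w(k,l) * W(k,l) * Z(j+1,l-1) to stay
// O(n^3) time / O(n^2) space.
//
// P(i,j) = w(i,j) * Z(i+1,j-1) * W(i,j) / Z; p_paired(i) = sum_j P(i,j).

// [[Rcpp::export]]
List mccaskill_pf(IntegerVector enc, NumericMatrix pw, int minh) {
  const int n = enc.size();
  const int m = n + 2;
  std::vector<double> Z((size_t)m * m, 0.0);
  auto id = [m](int i, int j) { return (size_t)i * m + j; };
  auto wt = [&](int i, int j) -> double {
    if (j - i <= minh) return 0.0;
    return pw(enc[i - 1] - 1, enc[j - 1] - 1);
  };
  auto Zg = [&](int i, int j) -> double {
    return (i > j) ? 1.0 : Z[id(i, j)];
  };

  for (int d = 0; d < n; ++d) {
    for (int i = 1; i + d <= n; ++i) {
      const int j = i + d;
      double z = Zg(i, j - 1);
      for (int k = i; k <= j - minh - 1; ++k) {
        const double w = wt(k, j);
        if (w > 0.0) z += Zg(i, k - 1) * w * Zg(k + 1, j - 1);
      }
      Z[id(i, j)] = z;
    }
  }
  const double Ztot = Zg(1, n);

  std::vector<double> W((size_t)m * m, 0.0);
  std::vector<double> G((size_t)m * m, -1.0);  // memoised; -1 = not computed
  std::vector<double> p(n, 0.0);

  // decreasing span so every enclosing pair's W is ready before it is used
  for (int d = n - 1; d >= minh + 1; --d) {
    for (int i = 1; i + d <= n; ++i) {
      const int j = i + d;
      const double wij = wt(i, j);
      if (wij <= 0.0) continue;
      double wo = Zg(1, i - 1) * Zg(j + 1, n);
      for (int k = 1; k <= i - 1; ++k) {
        double g = G[id(k, j)];
        if (g < 0.0) {
          g = 0.0;
          for (int l = j + 1; l <= n; ++l) {
            const double wkl = wt(k, l);
            if (wkl > 0.0) g += wkl * W[id(k, l)] * Zg(j + 1, l - 1);
          }
          G[id(k, j)] = g;
        }
        if (g > 0.0) wo += Zg(k + 1, i - 1) * g;
      }
      W[id(i, j)] = wo;
      const double pij = wij * Zg(i + 1, j - 1) * wo / Ztot;
      p[i - 1] += pij;
      p[j - 1] += pij;
    }
  }

  return List::create(_["Z"] = Ztot,
                      _["p_paired"] = NumericVector(p.begin(), p.end()));
}
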