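#include <Rcpp.h>
using namespace Rcpp;

// Takahashi selected inverse from a sparse lower-triangular Cholesky
// factor L (column-compressed, diagonal first in each column, rows sorted
// ascending) with A = L L^T. Returns the entries of A^{-1} on the pattern
// of L (lower triangle including the diagonal).
//
// Recurrences (Erisman & Tinney 1975), using the unit factor
// Lu = L * diag(1/Ljj) and d_j = Ljj^2:
//   S[J, j] = -T Lu[J, j],  T = S[J, J],  J = struct(col j) below diag
//   S_jj    = 1/d_j - Lu[J, j] . S[J, j]
// for j = n-1 .. 0. Every S(i, k) referenced lies inside the filled
// pattern because J is a clique of the filled graph. The inner
// contraction uses a scatter of column min(i, k) into a dense workspace,
// so each pair costs O(1) after an O(nnz(col)) scatter.

// [[Rcpp::export(name = ".takahashi_cpp")]]
NumericVector takahashi_cpp(IntegerVector Lp, IntegerVector Li,
                            NumericVector Lx, int n) {
  std::vector<double> Sx(Lx.size(), 0.0);
  std::vector<double> work(n, 0.0);
  std::vector<int> tag(n, -1);
  std::vector<double> acc;   // accumulators for S[J, j]
  std::vector<int> posJ;     // positions of J entries within column j

  for (int j = n - 1; j >= 0; --j) {
    int p0 = Lp[j], p1 = Lp[j + 1];
    if (p0 >= p1) continue;
    double ljj = Lx[p0];
    int m = p1 - p0 - 1;
    if (m == 0) { Sx[p0] = 1.0 / (ljj * ljj); continue; }

    acc.assign(m, 0.0);
    posJ.resize(m);
    for (int a = 0; a < m; ++a) posJ[a] = p0 + 1 + a;

    // result[a] = sum_b T[a, b] * Lu[b]; T symmetric, pairs grouped by
    // the smaller index b so one scatter of column J[b] serves them all
    for (int b = 0; b < m; ++b) {
      int c = Li[posJ[b]];
      double lub = Lx[posJ[b]] / ljj;
      // scatter column c of S (rows >= c)
      for (int t = Lp[c]; t < Lp[c + 1]; ++t) {
        work[Li[t]] = Sx[t];
        tag[Li[t]] = c;
      }
      // diagonal pair (b, b)
      acc[b] += Lx[posJ[b]] / ljj * work[c];
      for (int a = b + 1; a < m; ++a) {
        int r = Li[posJ[a]];
        double s = (tag[r] == c) ? work[r] : 0.0;  // outside fill: 0
        double lua = Lx[posJ[a]] / ljj;
        acc[a] += lub * s;
        acc[b] += lua * s;
      }
    }
    double dacc = 1.0 / (ljj * ljj);
    for (int a = 0; a < m; ++a) {
      Sx[posJ[a]] = -acc[a];
      dacc += (Lx[posJ[a]] / ljj) * acc[a];
    }
    Sx[p0] = dacc;
  }
  return NumericVector(Sx.begin(), Sx.end());
}
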