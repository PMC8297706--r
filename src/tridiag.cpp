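#include <Rcpp.h>
using namespace Rcpp;

// Batched shifted tridiagonal solves: for each column j of B, solve
//   (T + shift[j] * I) x = B[, j]
// where T has subdiagonal dl (length n-1), diagonal d (length n) and
// superdiagonal du (length n-1). The shifted systems arising from the
// Kronecker-sum block solver are strictly diagonally dominant, so the
// Thomas algorithm without pivoting is stable.
// [[Rcpp::export]]
NumericMatrix tridiag_shift_solve(NumericVector dl, NumericVector d,
                                  NumericVector du, NumericVector shifts,
                                  NumericMatrix B) {
  const int n = d.size();
  const int m = B.ncol();
  if (B.nrow() != n) stop("B must have length(d) rows");
  if (shifts.size() != m) stop("one shift per column required");
  NumericMatrix X(n, m);
  std::vector<double> c(n), z(n);
  for (int j = 0; j < m; ++j) {
    const double s = shifts[j];
    // forward elimination
    double piv = d[0] + s;
    if (piv == 0.0) stop("singular shifted tridiagonal system");
    c[0] = (n > 1) ? du[0] / piv : 0.0;
    z[0] = B(0, j) / piv;
    for (int i = 1; i < n; ++i) {
      piv = (d[i] + s) - dl[i - 1] * c[i - 1];
      if (piv == 0.0) stop("singular shifted tridiagonal system");
      c[i] = (i < n - 1) ? du[i] / piv : 0.0;
      z[i] = (B(i, j) - dl[i - 1] * z[i - 1]) / piv;
    }
    // back substitution
    X(n - 1, j) = z[n - 1];
    for (int i = n - 2; i >= 0; --i)
      X(i, j) = z[i] - c[i] * X(i + 1, j);
  }
  return X;
}
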