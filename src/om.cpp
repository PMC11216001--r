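#include <Rcpp.h>
using namespace Rcpp;

// Optimal-matching (edit) distance between two integer-coded state
// sequences: minimum total cost of substitutions (cost matrix `sub`) and
// insertions/deletions (cost `indel`), by dynamic programming.
static double om_pair(const IntegerMatrix& seqs, int a, int b,
                      const NumericMatrix& sub, double indel,
                      std::vector<double>& d0, std::vector<double>& d1) {
  const int T = seqs.ncol();
  for (int j = 0; j <= T; ++j) d0[j] = j * indel;
  for (int i = 1; i <= T; ++i) {
    d1[0] = i * indel;
    const int ai = seqs(a, i - 1) - 1;
    for (int j = 1; j <= T; ++j) {
      const int bj = seqs(b, j - 1) - 1;
      double best = d0[j - 1] + sub(ai, bj);
      const double del = d0[j] + indel;
      const double ins = d1[j - 1] + indel;
      if (del < best) best = del;
      if (ins < best) best = ins;
      d1[j] = best;
    }
    d0.swap(d1);
  }
  return d0[T];
}

// [[Rcpp::export(name = ".om_dist_matrix_cpp")]]
NumericMatrix om_dist_matrix_cpp(IntegerMatrix seqs, NumericMatrix sub,
                                 double indel) {
  const int n = seqs.nrow(), T = seqs.ncol();
  std::vector<double> d0(T + 1), d1(T + 1);
  NumericMatrix D(n, n);
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) {
      const double d = om_pair(seqs, a, b, sub, indel, d0, d1);
      D(a, b) = d;
      D(b, a) = d;
    }
  return D;
}

// [[Rcpp::export(name = ".om_dist_pair_cpp")]]
double om_dist_pair_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                        double indel) {
  const int n = a.size(), m = b.size();
  std::vector<double> d0(m + 1), d1(m + 1);
  for (int j = 0; j <= m; ++j) d0[j] = j * indel;
  for (int i = 1; i <= n; ++i) {
    d1[0] = i * indel;
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      double best = d0[j - 1] + sub(ai, b[j - 1] - 1);
      const double del = d0[j] + indel;
      const double ins = d1[j - 1] + indel;
      if (del < best) best = del;
      if (ins < best) best = ins;
      d1[j] = best;
    }
    d0.swap(d1);
  }
  return d0[m];
}
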