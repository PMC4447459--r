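#include <Rcpp.h>
using namespace Rcpp;

// Count ordered triples x[i] < y[j] < z[k] where the group label of each
// element (1, 2 or 3) is given in sorted-value order.  `xs` must be sorted
// non-decreasing; `lab` gives the group of xs[i].  Strict inequalities:
// elements inside a tie block never count against each other.
static double triple_count_sorted(const NumericVector& xs,
                                  const IntegerVector& lab) {
  const int n = xs.size();
  // total group-3 elements
  int c3_total = 0;
  for (int i = 0; i < n; ++i) if (lab[i] == 3) ++c3_total;
  double count = 0.0;
  int c1 = 0;       // group-1 strictly below current tie block
  int c3_seen = 0;  // group-3 at or below current tie block
  int i = 0;
  while (i < n) {
    int j = i;
    int g1 = 0, g3 = 0;
    long g2 = 0;
    while (j < n && xs[j] == xs[i]) {
      if (lab[j] == 1) ++g1;
      else if (lab[j] == 2) ++g2;
      else ++g3;
      ++j;
    }
    if (g2 > 0) {
      const int c3_after = c3_total - c3_seen - g3;
      count += (double)g2 * (double)c1 * (double)c3_after;
    }
    c1 += g1;
    c3_seen += g3;
    i = j;
  }
  return count;
}

// [[Rcpp::export]]
double triple_count_cpp(NumericVector xs, IntegerVector lab) {
  return triple_count_sorted(xs, lab);
}

// Permutation driver: one probe, values pre-sorted; labmat holds one label
// assignment per row, already re-indexed to sorted-value order.  Returns the
// raw triple count for every row.
// [[Rcpp::export]]
NumericVector triple_count_perms_cpp(NumericVector xs, IntegerMatrix labmat) {
  const int B = labmat.nrow();
  const int n = xs.size();
  if (labmat.ncol() != n) stop("label matrix does not match value length");
  NumericVector out(B);
  IntegerVector lab(n);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) lab[i] = labmat(b, i);
    out[b] = triple_count_sorted(xs, lab);
  }
  return out;
}
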