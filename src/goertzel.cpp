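#include <Rcpp.h>
using namespace Rcpp;

// Multiplication-free Goertzel recursion at normalized frequency 1/3:
//   y[n] = x[n] - y[n-1] - y[n-2],  y[-1] = y[-2] = 0
// followed by the squared magnitude of the f = 1/3 bin,
//   P = y[N]^2 + y[N-1]^2 + y[N]*y[N-1].
// On 0/1 indicator input |y[n]| <= n, so 64-bit integers keep every
// intermediate exact for any realistic window length.
static inline double p3_power(const int* x, int n) {
  long long y1 = 0, y2 = 0; /* y[n-1], y[n-2] */
  for (int i = 0; i < n; ++i) {
    long long y = (long long)x[i] - y1 - y2;
    y2 = y1;
    y1 = y;
  }
  return (double)(y1 * y1 + y2 * y2 + y1 * y2);
}

// [[Rcpp::export(name = ".goertzel_p3_cpp")]]
double goertzel_p3_cpp(IntegerVector x) {
  if (x.size() == 0) stop("empty input vector");
  return p3_power(INTEGER(x), (int)x.size());
}

// Combined (A+C+G+T) window powers for `n_windows` consecutive windows
// starting at window index `first_window`; window start in residues is
// index * step (0-based). Each window is recomputed from scratch.
// [[Rcpp::export(name = ".scan_p3_cpp")]]
NumericVector scan_p3_cpp(IntegerVector a, IntegerVector c, IntegerVector g,
                          IntegerVector t, int window, int step,
                          int first_window, int n_windows) {
  int L = (int)a.size();
  if (c.size() != L || g.size() != L || t.size() != L)
    stop("indicator vectors must have equal length");
  if (window < 3 || step < 1 || first_window < 0 || n_windows < 0)
    stop("invalid scan geometry");
  const int *pa = INTEGER(a), *pc = INTEGER(c), *pg = INTEGER(g), *pt = INTEGER(t);
  NumericVector out(n_windows);
  for (int wi = 0; wi < n_windows; ++wi) {
    int s = (first_window + wi) * step;
    if (s + window > L) stop("window exceeds sequence length");
    out[wi] = p3_power(pa + s, window) + p3_power(pc + s, window) +
              p3_power(pg + s, window) + p3_power(pt + s, window);
  }
  return out;
}
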