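#include <Rcpp.h>
using namespace Rcpp;

// All-pairs shortest paths on a dense nonnegative weight matrix.
// Missing edges are encoded as R_PosInf; the diagonal must be zero.
// Loop order k-j-i keeps the inner loop contiguous in the column-major
// storage (columns k and j), which matters because this sits in the GA
// fitness hot path.
// [[Rcpp::export(name = ".fw_shortest_paths")]]
NumericMatrix fw_shortest_paths(NumericMatrix w) {
  int n = w.nrow();
  NumericMatrix out(clone(w));
  double *d = out.begin();
  for (int k = 0; k < n; ++k) {
    const double *dk = d + (size_t)n * k;   // column k: d(i, k)
    for (int j = 0; j < n; ++j) {
      double dkj = d[k + (size_t)n * j];
      if (dkj == R_PosInf) continue;
      double *dj = d + (size_t)n * j;       // column j: d(i, j)
      for (int i = 0; i < n; ++i) {
        double alt = dk[i] + dkj;
        if (alt < dj[i]) dj[i] = alt;
      }
    }
  }
  return out;
}
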