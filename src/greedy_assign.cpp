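#include <Rcpp.h>
using namespace Rcpp;

// Greedy nearest-neighbour assignment without replacement between two point
// sets: for each original vertex (visited in the supplied order), pick the
// nearest rotated vertex not yet taken. Returns a 1-based permutation p with
// p[i] = source vertex whose value lands on position i. With an identity
// rotation every vertex keeps its own position regardless of visit order.
// The pool of unassigned candidates is compacted with swap-removal so each
// scan only touches what is left.

// [[Rcpp::export(name = "greedyAssign")]]
IntegerVector greedyAssign(NumericMatrix original, NumericMatrix rotated,
                           IntegerVector order) {
  const int n = original.nrow();
  IntegerVector out(n);
  std::vector<int> pool(n);
  for (int j = 0; j < n; ++j) pool[j] = j;
  std::vector<double> rx(n), ry(n), rz(n);
  for (int j = 0; j < n; ++j) {
    rx[j] = rotated(j, 0); ry[j] = rotated(j, 1); rz[j] = rotated(j, 2);
  }
  int remaining = n;
  for (int oi = 0; oi < n; ++oi) {
    const int i = order[oi] - 1;
    const double xi = original(i, 0), yi = original(i, 1), zi = original(i, 2);
    int bestSlot = 0;
    double bestD = R_PosInf;
    for (int s = 0; s < remaining; ++s) {
      const int j = pool[s];
      const double dx = xi - rx[j], dy = yi - ry[j], dz = zi - rz[j];
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < bestD) { bestD = d; bestSlot = s; }
    }
    out[i] = pool[bestSlot] + 1;
    pool[bestSlot] = pool[--remaining];
  }
  return out;
}
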