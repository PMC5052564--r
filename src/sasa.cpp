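#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley point-burial kernel. xyz: n x 3 atom coordinates, rad:
// expanded radii (vdw + probe), pts: m x 3 unit-sphere test directions
// (already oriented in the molecule frame). Returns per-atom SASA.
// [[Rcpp::export(name = ".sasa_kernel")]]
NumericVector sasa_kernel(const NumericMatrix& xyz,
                          const NumericVector& rad,
                          const NumericMatrix& pts) {
  const int n = xyz.nrow();
  const int m = pts.nrow();
  NumericVector out(n);
  std::vector<int> nbr;
  nbr.reserve(n);
  for (int i = 0; i < n; ++i) {
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    const double ri = rad[i];
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi,
                   dz = xyz(j, 2) - zi;
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double rr = ri + rad[j];
      if (d2 < rr * rr && d2 > 1e-12) nbr.push_back(j);
    }
    int n_free = 0;
    for (int k = 0; k < m; ++k) {
      const double px = xi + ri * pts(k, 0);
      const double py = yi + ri * pts(k, 1);
      const double pz = zi + ri * pts(k, 2);
      bool free_pt = true;
      for (size_t q = 0; q < nbr.size(); ++q) {
        const int j = nbr[q];
        const double dx = px - xyz(j, 0), dy = py - xyz(j, 1),
                     dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < rad[j] * rad[j]) {
          free_pt = false;
          // move the burying neighbour to the front: consecutive points
          // are spatial neighbours on the spiral, so this amortizes well
          if (q > 0) std::swap(nbr[0], nbr[q]);
          break;
        }
      }
      if (free_pt) ++n_free;
    }
    out[i] = 4.0 * M_PI * ri * ri * ((double) n_free / m);
  }
  return out;
}
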