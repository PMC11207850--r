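#include <Rcpp.h>
using namespace Rcpp;

// Forward-time centred-space diffusion step in conservative form with
// spatially varying diffusivity. Interface diffusivity is the arithmetic
// mean of the adjacent voxel values; out-of-grid neighbours carry no flux
// (sealed, zero-flux boundaries). Voxels listed in clamp_idx (1-based) are
// held at the bath occupancy b before and after every step, which realises
// the Dirichlet condition on exposed faces and defect voxels.
//
// u:     occupancy grid (n1*n2*n3, column-major)
// dvox:  voxel diffusivity in um^2/s, same layout
// coef:  dt / h^2 (s per um^2)
// [[Rcpp::export]]
NumericVector step_ftcs_cpp(NumericVector u, NumericVector dvox,
                            IntegerVector dims, IntegerVector clamp_idx,
                            double b, double coef, int n_steps) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector cur = clone(u);
  NumericVector nxt(n);
  double *a = REAL(cur), *w = REAL(nxt);
  const double *D = REAL(dvox);
  const int *cl = INTEGER(clamp_idx);
  const R_xlen_t ncl = clamp_idx.size();
  const R_xlen_t s1 = 1, s2 = n1, s3 = (R_xlen_t)n1 * n2;

  for (R_xlen_t c = 0; c < ncl; ++c) a[cl[c] - 1] = b;

  for (int step = 0; step < n_steps; ++step) {
    for (int k = 0; k < n3; ++k) {
      for (int j = 0; j < n2; ++j) {
        const R_xlen_t base = j * s2 + k * s3;
        for (int i = 0; i < n1; ++i) {
          const R_xlen_t id = base + i;
          const double ui = a[id], Di = D[id];
          double acc = 0.0;
          if (i > 0)      acc += 0.5 * (Di + D[id - s1]) * (a[id - s1] - ui);
          if (i < n1 - 1) acc += 0.5 * (Di + D[id + s1]) * (a[id + s1] - ui);
          if (j > 0)      acc += 0.5 * (Di + D[id - s2]) * (a[id - s2] - ui);
          if (j < n2 - 1) acc += 0.5 * (Di + D[id + s2]) * (a[id + s2] - ui);
          if (k > 0)      acc += 0.5 * (Di + D[id - s3]) * (a[id - s3] - ui);
          if (k < n3 - 1) acc += 0.5 * (Di + D[id + s3]) * (a[id + s3] - ui);
          w[id] = ui + coef * acc;
        }
      }
    }
    for (R_xlen_t c = 0; c < ncl; ++c) w[cl[c] - 1] = b;
    std::swap(a, w);
  }
  if (a == REAL(cur)) return cur;
  return nxt;
}
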