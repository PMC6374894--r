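#include <Rcpp.h>
using namespace Rcpp;

// Count, for every unordered gene pair (i < j, row order), in how many
// samples gene i is strictly above gene j (s_ij) and in how many either
// strict ordering holds (n_eff); ties contribute to neither.  Pairs are
// emitted in row-major upper-triangle order: (1,2), (1,3), ..., (G-1,G).
// [[Rcpp::export]]
List pair_counts_cpp(NumericMatrix x) {
  const int g = x.nrow(), s = x.ncol();
  if (g < 2) stop("need at least two genes");
  const R_xlen_t np = (R_xlen_t)g * (g - 1) / 2;
  IntegerVector s_ij(np), n_eff(np);
  // column-major copy for contiguous per-gene access
  std::vector<double> xv((size_t)g * s);
  for (int k = 0; k < s; ++k)
    for (int i = 0; i < g; ++i)
      xv[(size_t)i * s + k] = x(i, k);
  R_xlen_t idx = 0;
  for (int i = 0; i < g - 1; ++i) {
    const double *xi = &xv[(size_t)i * s];
    for (int j = i + 1; j < g; ++j, ++idx) {
      const double *xj = &xv[(size_t)j * s];
      int w = 0, l = 0;
      for (int k = 0; k < s; ++k) {
        if (xi[k] > xj[k]) ++w;
        else if (xj[k] > xi[k]) ++l;
      }
      s_ij[idx] = w;
      n_eff[idx] = w + l;
    }
  }
  return List::create(_["s_ij"] = s_ij, _["n_eff"] = n_eff);
}
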