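#include <Rcpp.h>
using namespace Rcpp;

// Grouped maxima over a partition of an H x W x k response array.
// breaks_r / breaks_c are 0-based bin edges of length n_r+1 / n_c+1
// (monotone increasing, first 0, last H resp. W). Returns n_r x n_c x k.
// [[Rcpp::export]]
NumericVector cpp_pool_max(NumericVector resp, IntegerVector breaks_r,
                           IntegerVector breaks_c) {
  IntegerVector dim = resp.attr("dim");
  if (dim.size() != 3) stop("`resp` must be a 3-d array");
  const int H = dim[0], W = dim[1], k = dim[2];
  const int nr = breaks_r.size() - 1, nc = breaks_c.size() - 1;
  if (breaks_r[0] != 0 || breaks_r[nr] != H || breaks_c[0] != 0 ||
      breaks_c[nc] != W)
    stop("bin edges must span the full response map");
  NumericVector out(static_cast<R_xlen_t>(nr) * nc * k);
  out.attr("dim") = IntegerVector::create(nr, nc, k);
  const double* x = REAL(resp);
  double* o = REAL(out);
  for (int f = 0; f < k; ++f) {
    const double* plane = x + static_cast<R_xlen_t>(f) * H * W;
    for (int cj = 0; cj < nc; ++cj) {
      for (int ri = 0; ri < nr; ++ri) {
        if (breaks_r[ri + 1] <= breaks_r[ri] || breaks_c[cj + 1] <= breaks_c[cj])
          stop("empty subregion: grid finer than the response map");
        double m = R_NegInf;
        for (int c = breaks_c[cj]; c < breaks_c[cj + 1]; ++c) {
          const double* col = plane + static_cast<R_xlen_t>(c) * H;
          for (int r = breaks_r[ri]; r < breaks_r[ri + 1]; ++r)
            if (col[r] > m) m = col[r];
        }
        o[static_cast<R_xlen_t>(f) * nr * nc +
          static_cast<R_xlen_t>(cj) * nr + ri] = m;
      }
    }
  }
  return out;
}
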