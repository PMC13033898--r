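#include <Rcpp.h>
using namespace Rcpp;

// Complex AR(1) (discrete Ornstein-Uhlenbeck) speckle stream with stationary
// amplitude `sigma` (E|x|^2 = sigma^2). `rho` is either length 1 (static
// dynamics) or length n; rho[i-1] governs the update from sample i-1 to i so a
// time-varying decay rate acts causally. Innovations come from R's RNG, so a
// prior set.seed() makes the stream reproducible.
// [[Rcpp::export(name = ".cx_ar1_stream")]]
ComplexVector cx_ar1_stream(int n, NumericVector rho, double sigma) {
  ComplexVector out(n);
  const bool varying = rho.size() > 1;
  const double s2 = sigma / std::sqrt(2.0);  // per-quadrature sd
  double re = norm_rand() * s2;
  double im = norm_rand() * s2;
  out[0].r = re;
  out[0].i = im;
  for (int i = 1; i < n; ++i) {
    const double r = varying ? rho[i - 1] : rho[0];
    const double q = std::sqrt(std::max(0.0, 1.0 - r * r)) * s2;
    re = r * re + norm_rand() * q;
    im = r * im + norm_rand() * q;
    out[i].r = re;
    out[i].i = im;
  }
  return out;
}

// Blocked field autocorrelation: for each block offset r*stride, compute
// G1(j) = (1/(block-j)) * sum_i conj(x[i]) * x[i+j]  (unbiased pair count).
// Returns an (n_records x (max_lag+1)) complex matrix; lag 0 is included in
// the output but excluded from downstream analysis by the callers.
// [[Rcpp::export(name = ".g1_blocked")]]
ComplexMatrix g1_blocked(ComplexVector x, int block, int stride, int max_lag) {
  const int n = x.size();
  if (block > n) stop("stream shorter than one block");
  if (max_lag >= block) stop("max_lag must be smaller than the block length");
  if (stride < 1) stop("stride must be positive");
  const int nrec = (n - block) / stride + 1;
  ComplexMatrix out(nrec, max_lag + 1);
  for (int r = 0; r < nrec; ++r) {
    const int off = r * stride;
    for (int j = 0; j <= max_lag; ++j) {
      double sr = 0.0, si = 0.0;
      const int m = block - j;
      for (int i = 0; i < m; ++i) {
        const Rcomplex &a = x[off + i];
        const Rcomplex &b = x[off + i + j];
        sr += a.r * b.r + a.i * b.i;  // Re{conj(a) * b}
        si += a.r * b.i - a.i * b.r;  // Im{conj(a) * b}
      }
      out(r, j).r = sr / m;
      out(r, j).i = si / m;
    }
  }
  return out;
}
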