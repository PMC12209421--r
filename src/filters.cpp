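// Stateful IIR filtering and polyphase FIR resampling.

#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

// Direct-form-II-transposed IIR filter applied along the columns-as-time of a
// channels x time matrix, with explicit per-channel state so that chunked
// streaming and whole-record filtering agree exactly.
// b, a: coefficients with a(0) == 1 (normalized by caller).
// zi: channels x (max(len(a),len(b)) - 1) initial state (zeros for fresh).
// Returns list(y, zf).
// [[Rcpp::export]]
List iir_filter_cpp(const arma::vec& b, const arma::vec& a,
                    const arma::mat& x, const arma::mat& zi) {
  const int C = x.n_rows, T = x.n_cols;
  const int nb = b.n_elem, na = a.n_elem;
  const int ns = std::max(nb, na) - 1;
  vec bb(ns + 1, fill::zeros), aa(ns + 1, fill::zeros);
  bb.head(nb) = b;
  aa.head(na) = a;
  mat y(C, T), z = zi;
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < T; ++t) {
      double xn = x(c, t);
      double yn = bb(0) * xn + (ns > 0 ? z(c, 0) : 0.0);
      for (int k = 0; k < ns - 1; ++k)
        z(c, k) = bb(k + 1) * xn + z(c, k + 1) - aa(k + 1) * yn;
      if (ns > 0)
        z(c, ns - 1) = bb(ns) * xn - aa(ns) * yn;
      y(c, t) = yn;
    }
  }
  return List::create(_["y"] = y, _["zf"] = z);
}

// Polyphase rational resampling by up/down with FIR h (odd-length, linear
// phase).  Equivalent to: upsample by `up` (zero-stuffing), filter with h,
// downsample by `down`, with the output aligned so that the FIR group delay
// (len(h)-1)/2 is compensated.  Operates on each row of x.
// [[Rcpp::export]]
arma::mat upfirdn_cpp(const arma::mat& x, const arma::vec& h,
                      int up, int down, int n_out) {
  const int C = x.n_rows, T = x.n_cols, Lh = h.n_elem;
  const int delay = (Lh - 1) / 2;   // in upsampled samples
  mat y(C, n_out, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < n_out; ++j) {
      // output j corresponds to upsampled index m = j*down + delay
      const long m = (long)j * down + delay;
      // y = sum_k h(k) * xu(m - k), xu nonzero at multiples of `up`
      long kstart = m % up;         // smallest k with (m-k) % up == 0
      for (long k = kstart; k < Lh; k += up) {
        long iu = (m - k) / up;
        if (iu >= 0 && iu < T) y(c, j) += h(k) * x(c, iu);
      }
    }
  }
  return y;
}
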