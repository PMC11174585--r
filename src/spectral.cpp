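// Batched spectral filtering kernel for the frequency-domain GCN layer.
//
// Feature batches are laid out as real cubes (S spatial bins x T frames x N
// items) with S = C*V (channel-fastest flattening). The layer multiplies the
// unnormalised 2D DFT of each slice by a real separable mask M = ms * mt',
// where ms has already been symmetrised across mirrored spatial bins and mt
// is even in the temporal frequency, so M is Hermitian-compatible and the
// inverse transform is exactly real. Orthonormal scaling cancels between the
// forward and inverse transforms, so the unnormalised pair used here computes
// the same operator; mask gradients are rescaled by 1/(S*T) on the R side to
// match the orthonormal convention.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List spec_forward_cpp(const arma::cube& x, const arma::vec& ms,
                            const arma::vec& mt_full) {
  const uword S = x.n_rows, T = x.n_cols, N = x.n_slices;
  if (ms.n_elem != S || mt_full.n_elem != T)
    Rcpp::stop("mask length does not match feature dimensions");
  cube y(S, T, N);
  cx_cube fx(S, T, N);
  mat M = ms * mt_full.t();
  cx_mat Mc = cx_mat(M, zeros<mat>(S, T));
  for (uword n = 0; n < N; ++n) {
    cx_mat F = fft2(x.slice(n));
    fx.slice(n) = F;
    y.slice(n) = real(ifft2(cx_mat(F % Mc)));
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("fx") = fx);
}

// [[Rcpp::export]]
Rcpp::List spec_backward_cpp(const arma::cube& dy, const arma::cx_cube& fx,
                             const arma::vec& ms, const arma::vec& mt_full) {
  const uword S = dy.n_rows, T = dy.n_cols, N = dy.n_slices;
  cube dx(S, T, N);
  mat G(S, T, fill::zeros);  // Re(conj(fft2(dy)) % fx), summed over items
  mat M = ms * mt_full.t();
  cx_mat Mc = cx_mat(M, zeros<mat>(S, T));
  for (uword n = 0; n < N; ++n) {
    cx_mat Fd = fft2(dy.slice(n));
    G += real(conj(Fd) % fx.slice(n));
    dx.slice(n) = real(ifft2(cx_mat(Fd % Mc)));
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("G") = G);
}

// Plain batched spectral filter application without caches (inference path).
// [[Rcpp::export]]
arma::cube spec_apply_cpp(const arma::cube& x, const arma::vec& ms,
                          const arma::vec& mt_full) {
  const uword S = x.n_rows, T = x.n_cols, N = x.n_slices;
  cube y(S, T, N);
  mat M = ms * mt_full.t();
  cx_mat Mc = cx_mat(M, zeros<mat>(S, T));
  for (uword n = 0; n < N; ++n) {
    y.slice(n) = real(ifft2(cx_mat(fft2(x.slice(n)) % Mc)));
  }
  return y;
}
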