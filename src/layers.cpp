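// Batched forward/backward kernels for the spectral GCN layer and the
// fixed-window temporal-convolution baseline layer.
//
// Feature batches arrive as cubes (C, V, T*N): channel-fastest, joints
// second, frames*items last, matching the R array layout (C, V, T, N). The
// (C, V) block is contiguous, so the same memory reinterprets as the
// (S = C*V, T, N) cube the 2D spectral filter operates on. M is the
// degree-normalised edge-weight aggregation matrix (row i mixes the
// neighbourhood of joint i), ms/mt_full the activated (and, for ms,
// symmetrised) spectral mask factors.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline void leaky_inplace(cube& x, double slope) {
  x.transform([slope](double v) { return v >= 0 ? v : slope * v; });
}

// [[Rcpp::export]]
Rcpp::List fgcn_layer_fwd_cpp(const arma::cube& x, const arma::mat& w_proj,
                              const arma::vec& b, const arma::mat& m_agg,
                              const bool spectral, const arma::vec& ms,
                              const arma::vec& mt_full, const double slope,
                              const int t_frames, const int n_items) {
  const uword C_in = x.n_rows, V = x.n_cols, TN = x.n_slices;
  const uword C_out = w_proj.n_rows;
  const uword T = (uword)t_frames, N = (uword)n_items;
  if (T * N != TN) Rcpp::stop("frames*items does not match batch");

  // channel projection as one big GEMM
  const mat xm(const_cast<double*>(x.memptr()), C_in, V * TN, false, true);
  cube h(C_out, V, TN);
  mat hm(h.memptr(), C_out, V * TN, false, true);
  hm = w_proj * xm;
  hm.each_col() += b;

  // per-(frame,item) neighbourhood aggregation: Z = H * M'
  cube z(C_out, V, TN);
  const mat mt_agg = m_agg.t();
  for (uword i = 0; i < TN; ++i) z.slice(i) = h.slice(i) * mt_agg;
  cube a = z;
  leaky_inplace(a, slope);

  cube y;
  cx_cube fx;
  if (spectral) {
    const uword S = C_out * V;
    y.set_size(C_out, V, TN);
    fx.set_size(S, T, N);
    mat mask = ms * mt_full.t();
    cx_mat maskc(mask, zeros<mat>(S, T));
    for (uword n = 0; n < N; ++n) {
      const mat a_n(const_cast<double*>(a.memptr()) + n * S * T, S, T,
                    false, true);
      mat y_n(y.memptr() + n * S * T, S, T, false, true);
      cx_mat f = fft2(a_n);
      fx.slice(n) = f;
      y_n = real(ifft2(cx_mat(f % maskc)));
    }
  } else {
    y = a;
  }
  cube out = y;
  out.transform([](double v) { return v > 0 ? v : 0.0; });
  return Rcpp::List::create(
    Rcpp::Named("out") = out, Rcpp::Named("h") = h, Rcpp::Named("a") = a,
    Rcpp::Named("y") = y, Rcpp::Named("fx") = fx);
}

// [[Rcpp::export]]
Rcpp::List fgcn_layer_bwd_cpp(const arma::cube& dout, const arma::cube& x,
                              const arma::cube& h, const arma::cube& a,
                              const arma::cube& y, const arma::cx_cube& fx,
                              const arma::mat& w_proj, const arma::mat& m_agg,
                              const bool spectral, const arma::vec& ms,
                              const arma::vec& mt_full, const double slope,
                              const int t_frames, const int n_items) {
  const uword C_out = dout.n_rows, V = dout.n_cols, TN = dout.n_slices;
  const uword C_in = x.n_rows;
  const uword T = (uword)t_frames, N = (uword)n_items;

  cube dy = dout;
  for (uword i = 0; i < TN; ++i) {
    const mat& ys = y.slice(i);
    dy.slice(i) %= conv_to<mat>::from(ys > 0);
  }

  cube da(C_out, V, TN);
  mat g_mask;
  if (spectral) {
    const uword S = C_out * V;
    g_mask.zeros(S, T);
    mat mask = ms * mt_full.t();
    cx_mat maskc(mask, zeros<mat>(S, T));
    for (uword n = 0; n < N; ++n) {
      const mat dy_n(const_cast<double*>(dy.memptr()) + n * S * T, S, T,
                     false, true);
      mat da_n(da.memptr() + n * S * T, S, T, false, true);
      cx_mat fd = fft2(dy_n);
      g_mask += real(conj(fd) % fx.slice(n));
      da_n = real(ifft2(cx_mat(fd % maskc)));
    }
    g_mask /= (double)(S * T);  // orthonormal-convention scaling
  } else {
    da = dy;
  }

  // through the LeakyReLU of the aggregation (sign(a) == sign(z))
  cube dz = da;
  for (uword i = 0; i < TN; ++i) {
    const mat& as = a.slice(i);
    dz.slice(i) %= (conv_to<mat>::from(as >= 0) * (1.0 - slope) + slope);
  }

  mat dm(V, V, fill::zeros);
  cube dh(C_out, V, TN);
  for (uword i = 0; i < TN; ++i) {
    dm += dz.slice(i).t() * h.slice(i);
    dh.slice(i) = dz.slice(i) * m_agg;
  }

  const mat xm(const_cast<double*>(x.memptr()), C_in, V * TN, false, true);
  mat dhm(dh.memptr(), C_out, V * TN, false, true);
  mat dw = dhm * xm.t();
  vec db = sum(dhm, 1);
  cube dx(C_in, V, TN);
  mat dxm(dx.memptr(), C_in, V * TN, false, true);
  dxm = w_proj.t() * dhm;

  return Rcpp::List::create(
    Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw, Rcpp::Named("db") = db,
    Rcpp::Named("dm") = dm, Rcpp::Named("g") = g_mask);
}

// [[Rcpp::export]]
Rcpp::List tcn_layer_fwd_cpp(const arma::cube& x, const arma::mat& w_proj,
                             const arma::vec& b, const arma::mat& adj,
                             const arma::mat& kern, const int t_frames,
                             const int n_items) {
  const uword C_in = x.n_rows, V = x.n_cols, TN = x.n_slices;
  const uword C_out = w_proj.n_rows;
  const uword T = (uword)t_frames, N = (uword)n_items;
  const uword s_d = kern.n_cols;

  const mat xm(const_cast<double*>(x.memptr()), C_in, V * TN, false, true);
  cube h(C_out, V, TN);
  mat hm(h.memptr(), C_out, V * TN, false, true);
  hm = w_proj * xm;
  hm.each_col() += b;

  cube nb(C_out, V, TN);
  for (uword i = 0; i < TN; ++i) nb.slice(i) = h.slice(i) * adj;  // adj sym

  cube z(C_out, V, TN, fill::zeros);
  for (uword n = 0; n < N; ++n) {
    for (uword t = 0; t < T; ++t) {
      mat zs(z.memptr() + (n * T + t) * C_out * V, C_out, V, false, true);
      for (uword tau = 0; tau < s_d && t + tau < T; ++tau) {
        const mat nbs(const_cast<double*>(nb.memptr()) +
                      (n * T + t + tau) * C_out * V, C_out, V, false, true);
        zs += nbs.each_col() % kern.col(tau);
      }
    }
  }
  cube out = z;
  out.transform([](double v) { return v > 0 ? v : 0.0; });
  return Rcpp::List::create(
    Rcpp::Named("out") = out, Rcpp::Named("nb") = nb, Rcpp::Named("z") = z);
}

// [[Rcpp::export]]
Rcpp::List tcn_layer_bwd_cpp(const arma::cube& dout, const arma::cube& x,
                             const arma::cube& nb, const arma::cube& z,
                             const arma::mat& w_proj, const arma::mat& adj,
                             const arma::mat& kern, const int t_frames,
                             const int n_items) {
  const uword C_out = dout.n_rows, V = dout.n_cols, TN = dout.n_slices;
  const uword C_in = x.n_rows;
  const uword T = (uword)t_frames, N = (uword)n_items;
  const uword s_d = kern.n_cols;

  cube dz = dout;
  for (uword i = 0; i < TN; ++i) {
    const mat& zs = z.slice(i);
    dz.slice(i) %= conv_to<mat>::from(zs > 0);
  }

  mat dkern(C_out, s_d, fill::zeros);
  cube dnb(C_out, V, TN, fill::zeros);
  for (uword n = 0; n < N; ++n) {
    for (uword t = 0; t < T; ++t) {
      const mat dzs(const_cast<double*>(dz.memptr()) +
                    (n * T + t) * C_out * V, C_out, V, false, true);
      for (uword tau = 0; tau < s_d && t + tau < T; ++tau) {
        const mat nbs(const_cast<double*>(nb.memptr()) +
                      (n * T + t + tau) * C_out * V, C_out, V, false, true);
        dkern.col(tau) += sum(dzs % nbs, 1);
        mat dnbs(dnb.memptr() + (n * T + t + tau) * C_out * V, C_out, V,
                 false, true);
        dnbs += dzs.each_col() % kern.col(tau);
      }
    }
  }

  cube dh(C_out, V, TN);
  for (uword i = 0; i < TN; ++i) dh.slice(i) = dnb.slice(i) * adj;

  const mat xm(const_cast<double*>(x.memptr()), C_in, V * TN, false, true);
  mat dhm(dh.memptr(), C_out, V * TN, false, true);
  mat dw = dhm * xm.t();
  vec db = sum(dhm, 1);
  cube dx(C_in, V, TN);
  mat dxm(dx.memptr(), C_in, V * TN, false, true);
  dxm = w_proj.t() * dhm;

  return Rcpp::List::create(
    Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw, Rcpp::Named("db") = db,
    Rcpp::Named("dkern") = dkern);
}
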