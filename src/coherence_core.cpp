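// Batched smoothed wavelet-coherence core.
//
// One "chunk" is a set of neighbouring scales analysed at a common sampling
// rate.  For K signal pairs at once (K = 1 for a data map, K = n_surrogates
// for the Monte-Carlo null), computes the Morlet cross/auto wavelet spectra,
// applies Gaussian time smoothing (sd = time_smooth * scale / sqrt(2)) and a
// boxcar over scales spanning `oct_width` octaves, and returns the coherence
// matrices for the requested target scales.  Column-batched FFTs go through
// FFTW.

#include <RcppArmadillo.h>
#include <fftw3.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// In-place column-wise DFT of a complex matrix; sign = FFTW_FORWARD or
// FFTW_BACKWARD.  Backward transforms are normalized by 1/n_rows.
static void fft_cols(cx_mat& X, int sign) {
  int n = static_cast<int>(X.n_rows);
  fftw_complex* ptr = reinterpret_cast<fftw_complex*>(X.memptr());
  fftw_plan p = fftw_plan_many_dft(1, &n, static_cast<int>(X.n_cols),
                                   ptr, nullptr, 1, n,
                                   ptr, nullptr, 1, n,
                                   sign, FFTW_ESTIMATE);
  fftw_execute(p);
  fftw_destroy_plan(p);
  if (sign == FFTW_BACKWARD) X /= static_cast<double>(n);
}

// Morlet window (Torrence-Compo), sampled on the length-n DFT grid for a
// scale in samples; energy-normalized by sqrt(2*pi*s).
static vec morlet_win(uword n, double s, double omega0) {
  vec win(n, fill::zeros);
  const double norm = std::pow(datum::pi, -0.25) *
    std::sqrt(2.0 * datum::pi * s);
  for (uword k = 1; k <= n / 2; ++k) {
    const double w = 2.0 * datum::pi * static_cast<double>(k) / n;
    const double z = s * w - omega0;
    win[k] = norm * std::exp(-0.5 * z * z);
  }
  return win;
}

// DFT of a periodized unit-gain Gaussian kernel with sd in samples.
static vec gauss_resp(uword n, double sd) {
  vec g(n);
  for (uword k = 0; k < n; ++k) {
    const double kk = (k <= n / 2) ? static_cast<double>(k)
                                   : static_cast<double>(k) - n;
    const double w = 2.0 * datum::pi * kk / n;
    g[k] = std::exp(-0.5 * sd * sd * w * w);
  }
  return g;
}

// [[Rcpp::export(name = ".chunk_coherence_cpp")]]
Rcpp::List chunk_coherence_cpp(const arma::cx_mat& fx, const arma::cx_mat& fy,
                               const arma::vec& scales, double omega0,
                               double time_smooth, double oct_width,
                               const arma::uvec& targets) {
  const uword npad = fx.n_rows, K = fx.n_cols, ns = scales.n_elem;
  field<mat> A(ns), B(ns);
  field<cx_mat> C(ns);
  for (uword j = 0; j < ns; ++j) {
    // fold the 1/sqrt(s) scale weight into the window so A, B, C come out
    // weighted by 1/s
    const cx_vec win = conv_to<cx_vec>::from(
      morlet_win(npad, scales[j], omega0) / std::sqrt(scales[j]));
    cx_mat Wx = fx, Wy = fy;
    Wx.each_col() %= win;
    Wy.each_col() %= win;
    fft_cols(Wx, FFTW_BACKWARD);
    fft_cols(Wy, FFTW_BACKWARD);
    const cx_vec g = conv_to<cx_vec>::from(
      gauss_resp(npad, time_smooth * scales[j] / std::sqrt(2.0)));
    // pack the two real auto-spectra as Re/Im of one complex field; the
    // smoother's kernel is real, so they stay separated
    cx_mat P(square(real(Wx)) + square(imag(Wx)),
             square(real(Wy)) + square(imag(Wy)));
    fft_cols(P, FFTW_FORWARD);
    P.each_col() %= g;
    fft_cols(P, FFTW_BACKWARD);
    A(j) = real(P);
    B(j) = imag(P);
    cx_mat Cj = Wx % conj(Wy);
    fft_cols(Cj, FFTW_FORWARD);
    Cj.each_col() %= g;
    fft_cols(Cj, FFTW_BACKWARD);
    C(j) = Cj;
  }
  const vec lg = log2(scales);
  Rcpp::List out(targets.n_elem);
  for (uword t = 0; t < targets.n_elem; ++t) {
    const uword j = targets[t] - 1;  // 1-based from R
    mat As(npad, K, fill::zeros), Bs(npad, K, fill::zeros);
    cx_mat Cs(npad, K, fill::zeros);
    for (uword j2 = 0; j2 < ns; ++j2) {
      if (std::abs(lg[j2] - lg[j]) <= oct_width / 2 + 1e-12) {
        As += A(j2);
        Bs += B(j2);
        Cs += C(j2);
      }
    }
    mat r2 = square(abs(Cs)) /
      clamp(As % Bs, std::numeric_limits<double>::min(), datum::inf);
    r2 = clamp(r2, 0.0, 1.0);
    out[t] = r2;
  }
  return out;
}
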