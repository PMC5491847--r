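# Morlet continuous wavelet transform and the multirate engine behind the
# wavelet-coherence statistic.
#
# Conventions (Torrence-Compo style Morlet):
#   psi_hat(s*w) = pi^(-1/4) * exp(-(s*w - omega0)^2 / 2),  w > 0
#   Fourier period of scale s:  lambda = s * fourier_factor(omega0)
#   cone of influence e-folding time: sqrt(2) * s
# Coherence uses the smoothed cross/auto spectra
#   R^2 = |S(W_x conj(W_y)/s)|^2 / ( S(|W_x|^2/s) * S(|W_y|^2/s) )
# with S = Gaussian smoothing in time (sd = scale/sqrt(2), scalable) followed
# by a boxcar over scales spanning 0.6 octave.

fourier_factor <- function(omega0) (4 * pi) / (omega0 + sqrt(2 + omega0^2))

#' Scale (seconds) of the Morlet wavelet whose Fourier period is 1/f
#' @param f frequency in Hz.
#' @param omega0 Morlet center parameter.
#' @return scale in seconds.
#' @keywords internal
scale_for_freq <- function(f, omega0) (1 / f) / fourier_factor(omega0)

ifft <- function(z) fft(z, inverse = TRUE) / length(z)

imvfft <- function(z) mvfft(z, inverse = TRUE) / nrow(z)

# Morlet window sampled on the DFT angular-frequency grid of length n
# (rad/sample), for a scale expressed in samples.  Includes the
# sqrt(2*pi*s) energy normalization.
morlet_window <- function(n, scale_samp, omega0) {
  k <- seq_len(n) - 1L
  w <- ifelse(k <= n / 2, 2 * pi * k / n, 2 * pi * (k - n) / n)
  win <- numeric(n)
  pos <- w > 0
  win[pos] <- pi^(-0.25) * sqrt(2 * pi * scale_samp) *
    exp(-0.5 * (scale_samp * w[pos] - omega0)^2)
  win
}

# Frequency response of a (periodized) Gaussian smoothing kernel with the
# given sd in samples, on the DFT grid of length n.  Unit DC gain.
gauss_response <- function(n, sd_samp) {
  k <- seq_len(n) - 1L
  w <- ifelse(k <= n / 2, 2 * pi * k / n, 2 * pi * (k - n) / n)
  exp(-0.5 * (sd_samp * w)^2)
}

#' Morlet continuous wavelet transform
#'
#' Computes the complex CWT of a single channel on the configured frequency
#' grid via the FFT, with zero padding to suppress wrap-around.  Linear in
#' its argument; coefficient magnitudes peak at the grid frequency nearest a
#' sinusoid's frequency (inside the cone of influence).
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param cfg a [coherence_config()].
#' @return complex matrix (frequency x time) with attributes `freqs` (Hz),
#'   `times` (s), `coi` (per-time minimum reliable frequency, Hz).
#' @export
morlet_cwt <- function(x, fs, cfg = coherence_config()) {
  n <- length(x)
  freqs <- cfg$freqs
  scales <- scale_for_freq(freqs, cfg$omega0)       # seconds
  if (n < 2 * sqrt(2) * max(scales) * fs) {
    stop(sprintf(
      "signal too short: need >= %d samples to support the %0.3g Hz band",
      ceiling(2 * sqrt(2) * max(scales) * fs), min(freqs)))
  }
  npad <- stats::nextn(n + ceiling(8 * max(scales) * fs), 2)
  fx <- fft(c(x, numeric(npad - n)))
  W <- matrix(0i, length(freqs), n)
  for (j in seq_along(freqs)) {
    win <- morlet_window(npad, scales[j] * fs, cfg$omega0)
    W[j, ] <- ifft(fx * win)[seq_len(n)]
  }
  times <- (seq_len(n) - 1L) / fs
  structure(W, freqs = freqs, times = times,
            coi = coi_min_freq(times, n / fs, cfg$omega0))
}

# Minimum reliable frequency at each time, from the sqrt(2)*s e-folding rule.
coi_min_freq <- function(times, total_s, omega0) {
  d <- pmin(times, total_s - times)
  ff <- fourier_factor(omega0)
  ifelse(d <= 0, Inf, sqrt(2) / (ff * d))
}

# Exact FFT-based resampling of x to n_new samples (ideal low-pass).
fft_resample <- function(x, n_new) {
  n <- length(x)
  if (n_new >= n) return(x)
  X <- fft(x)
  hpos <- floor(n_new / 2) + 1L           # bins k = 0..floor(n_new/2)
  nneg <- n_new - hpos
  Xc <- c(X[seq_len(hpos)], X[(n - nneg + 1L):n])
  Re(fft(Xc, inverse = TRUE)) / n
}

# Split the (ascending) frequency grid into octave chunks below the top
# frequency; returns list of index vectors (core members of each chunk).
octave_chunks <- function(freqs) {
  ftop <- max(freqs)
  oct <- floor(log2(ftop / freqs) - 1e-9)
  oct[freqs == ftop] <- 0L
  split(seq_along(freqs), oct)
}

# Coherence of one frequency chunk, for K signal pairs at once.
#
# fx, fy: FFTs of the (padded or circular) signals, npad x K complex
# matrices.  All per-frequency work is fused into a handful of batched
# mvfft calls over npad x (ns*K) matrices (columns ordered surrogate-fastest
# within frequency); the two real auto-spectra ride through the linear
# Gaussian time smoother packed as one complex field (A + iB).  Returns a
# list over `targets` of npad x K coherence matrices in [0,1].
chunk_coherence <- function(fx, fy, scales_samp, omega0, time_smooth,
                            oct_width, targets) {
  .chunk_coherence_cpp(fx, fy, scales_samp, omega0, time_smooth, oct_width,
                       as.integer(targets))
}

# Multirate wavelet coherence of two equal-length signals.  Each octave of
# the frequency grid is processed at a decimated rate (~6x its top guard
# frequency), which leaves the statistic unchanged (it depends on scale only
# in physical units) while making long records cheap.  Rows are interpolated
# back onto a common output time grid.
cwt_coherence_engine <- function(x, y, fs, cfg) {
  n <- length(x)
  freqs <- cfg$freqs
  chunks <- octave_chunks(freqs)
  stride <- cfg$time_stride %||% max(1L, floor(fs / (6 * max(freqs))))
  tout <- (seq(1L, n, by = stride) - 1L) / fs
  vals <- matrix(NA_real_, length(freqs), length(tout))
  guard <- ceiling(cfg$scale_smooth_oct / 2 /
                     min(diff(log2(freqs))) + 1e-9)
  for (ch in chunks) {
    idx_g <- max(1L, min(ch) - guard):min(length(freqs), max(ch) + guard)
    f_hi <- max(freqs[idx_g])
    fs_c <- min(fs, 6 * f_hi)
    n_c <- max(32L, floor(n * fs_c / fs))
    if (n_c >= n) { n_c <- n; fs_c <- fs } else fs_c <- n_c * fs / n
    xc <- fft_resample(x, n_c)
    yc <- fft_resample(y, n_c)
    scales_samp <- scale_for_freq(freqs[idx_g], cfg$omega0) * fs_c
    npad <- stats::nextn(n_c + ceiling(8 * max(scales_samp)), 2)
    fxc <- matrix(fft(c(xc, numeric(npad - n_c))), ncol = 1)
    fyc <- matrix(fft(c(yc, numeric(npad - n_c))), ncol = 1)
    r2 <- chunk_coherence(fxc, fyc, scales_samp, cfg$omega0,
                          cfg$time_smooth, cfg$scale_smooth_oct,
                          match(ch, idx_g))
    tc <- (seq_len(n_c) - 1L) / fs_c
    for (ti in seq_along(ch)) {
      row <- r2[[ti]][seq_len(n_c), 1]
      vals[ch[ti], ] <- if (n_c == n && stride == 1L) row else {
        approx(tc, row, xout = tout, rule = 2)$y
      }
    }
  }
  vals <- pmin(pmax(vals, 0), 1)
  list(values = vals, freqs = freqs, times = tout,
       coi = coi_min_freq(tout, n / fs, cfg$omega0))
}

# AR(1) spectral density at physical frequency f (Hz) for a process sampled
# at `fs` with lag-1 autocorrelation r; unit innovation variance scale.
ar1_spectrum <- function(f, r, fs) {
  (1 - r^2) / (1 - 2 * r * cos(2 * pi * f / fs) + r^2)
}

lag1_autocorr <- function(x) {
  x <- x - mean(x)
  d <- sum(x^2)
  if (d <= 0) return(0)
  r <- sum(x[-1] * x[-length(x)]) / d
  max(min(r, 0.99), -0.99)
}

# Circularly stationary Gaussian surrogates (columns) with the given
# spectral amplitude on the length-`len` DFT grid.  Circular stationarity
# means every time point is statistically equivalent: no cone of influence,
# no padding.
circular_surrogates <- function(len, k, amp) {
  Z <- matrix(complex(real = rnorm(len * k), imaginary = rnorm(len * k)),
              len, k) * amp
  Re(imvfft(Z))
}

# Spectral amplitude for a surrogate model on the folded DFT grid of length
# `len` at rate fs_c.  For "spectrum", the decimated data's periodogram is
# averaged into the surrogate bins and lightly smoothed, so surrogates share
# the data's actual spectral shape -- necessary for calibration when the
# data were band-pass filtered (an AR(1) null cannot represent a 5-Hz
# high-pass edge and understates the null coherence just below it).
surrogate_amplitude <- function(x, fs, cfg, fs_c, len) {
  fphys <- pmin(seq_len(len) - 1L, len - (seq_len(len) - 1L)) * fs_c / len
  if (cfg$surrogate_model == "white") return(rep(1, len))
  if (cfg$surrogate_model == "ar1") {
    return(sqrt(ar1_spectrum(fphys, lag1_autocorr(x), fs)))
  }
  xc <- fft_resample(x, max(len, round(length(x) * fs_c / fs)))
  P <- Mod(fft(xc - mean(xc)))^2 / length(xc)
  fd <- pmin(seq_along(xc) - 1L, length(xc) - (seq_along(xc) - 1L)) *
    (fs_c / length(xc))
  hb <- floor(len / 2)
  grid <- (0:hb) * fs_c / len
  # within-bin geometric mean: preserves steep spectral edges (a linear
  # mean over a fast-rising spectrum biases the low side up), and the
  # chi-squared log-bias is a constant factor that coherence ignores
  P <- pmax(P, max(P) * 1e-15)
  S <- vapply(grid, function(f) {
    sel <- abs(fd - f) <= fs_c / (2 * len) + 1e-12 & fd > 0
    if (!any(sel)) return(NA_real_)
    exp(mean(log(P[sel])))
  }, numeric(1))
  S[is.na(S)] <- max(S, na.rm = TRUE) * 1e-12
  sqrt(S[1L + round(fphys / (fs_c / len))])
}

# Per-frequency (1 - alpha) null quantiles of the coherence statistic under
# independent surrogate pairs, using the same octave-chunked multirate
# scheme as the forward engine.  Surrogates are circular, so all of their
# time points contribute to the pooled null sample.
mc_threshold_engine <- function(x, y, fs, cfg) {
  freqs <- cfg$freqs
  chunks <- octave_chunks(freqs)
  thr <- numeric(length(freqs))
  guard <- ceiling(cfg$scale_smooth_oct / 2 /
                     min(diff(log2(freqs))) + 1e-9)
  K <- cfg$n_surrogates
  for (ch in chunks) {
    idx_g <- max(1L, min(ch) - guard):min(length(freqs), max(ch) + guard)
    f_hi <- max(freqs[idx_g]); f_lo <- min(freqs[idx_g])
    fs_c <- min(fs, 6 * f_hi)
    # long enough that the circular time smoother at the largest scale in
    # the chunk does not overlap itself appreciably
    len <- stats::nextn(ceiling(8 / f_lo * fs_c), 2)
    xs <- circular_surrogates(len, K,
                              surrogate_amplitude(x, fs, cfg, fs_c, len))
    ys <- circular_surrogates(len, K,
                              surrogate_amplitude(y, fs, cfg, fs_c, len))
    scales_samp <- scale_for_freq(freqs[idx_g], cfg$omega0) * fs_c
    r2 <- chunk_coherence(mvfft(xs), mvfft(ys), scales_samp, cfg$omega0,
                          cfg$time_smooth, cfg$scale_smooth_oct,
                          match(ch, idx_g))
    for (ti in seq_along(ch)) {
      thr[ch[ti]] <- quantile(r2[[ti]], probs = 1 - cfg$alpha_level,
                              names = FALSE)
    }
  }
  pmin(pmax(thr, .Machine$double.eps), 1 - .Machine$double.eps)
}
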