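# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: plain loops and textbook formulas.

# Welch magnitude-squared coherence with Hann windows, no overlap.
welch_coherence <- function(x, y, fs, nseg = 20) {
  n <- length(x)
  L <- floor(n / nseg)
  h <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))
  Cxy <- complex(real = numeric(L), imaginary = numeric(L))
  Sxx <- Syy <- numeric(L)
  for (i in seq_len(nseg)) {
    a <- (i - 1) * L
    X <- fft(h * x[(a + 1):(a + L)])
    Y <- fft(h * y[(a + 1):(a + L)])
    Cxy <- Cxy + X * Conj(Y)
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
  }
  list(freq = (seq_len(L) - 1) / L * fs,
       coh = Mod(Cxy)^2 / pmax(Sxx * Syy, .Machine$double.xmin))
}

# Mean Welch coherence of a channel pair of a task_signal in a band.
band_welch_coherence <- function(sig, ch_a, ch_b, band, nseg = 20) {
  w <- welch_coherence(sig$samples[ch_a, ], sig$samples[ch_b, ],
                       sig$fs, nseg)
  sel <- w$freq >= band[1] & w$freq <= band[2]
  mean(w$coh[sel])
}

# Analytic (1 - alpha) null bound for Welch coherence with K segments.
welch_null_bound <- function(K, alpha = 0.05) 1 - alpha^(1 / (K - 1))

# Brute-force single-loop Hudgins features.
zc_loop <- function(x, eps) {
  n <- 0L
  for (k in seq_len(length(x) - 1)) {
    if (x[k] * x[k + 1] < 0 && abs(x[k] - x[k + 1]) >= eps) n <- n + 1L
  }
  n
}
ssc_loop <- function(x, eps) {
  n <- 0L
  if (length(x) < 3) return(n)
  for (k in 2:(length(x) - 1)) {
    ext <- (x[k] > x[k - 1] && x[k] > x[k + 1]) ||
           (x[k] < x[k - 1] && x[k] < x[k + 1])
    if (ext && max(abs(x[k] - x[k + 1]), abs(x[k] - x[k - 1])) >= eps) {
      n <- n + 1L
    }
  }
  n
}
mav_loop <- function(x) { s <- 0; for (v in x) s <- s + abs(v); s / length(x) }
wl_loop <- function(x) {
  s <- 0
  for (k in seq_len(length(x) - 1)) s <- s + abs(x[k + 1] - x[k])
  s
}

# Interval union on a fine lattice (0.05 Hz), as a check of merge_bands.
lattice_union <- function(bands_list, lo = 0.5, hi = 100, step = 0.05) {
  grid <- seq(lo, hi, by = step)
  covered <- rep(FALSE, length(grid))
  for (b in bands_list) {
    for (i in seq_len(nrow(b))) {
      covered <- covered | (grid >= b$lo_hz[i] - 1e-9 &
                              grid <= b$hi_hz[i] + 1e-9)
    }
  }
  if (!any(covered)) return(data.frame(lo_hz = numeric(0), hi_hz = numeric(0)))
  r <- rle(covered)
  e <- cumsum(r$lengths); s <- e - r$lengths + 1L
  keep <- which(r$values)
  data.frame(lo_hz = grid[s[keep]], hi_hz = grid[e[keep]])
}

# Closed-form Gaussian Bayes posterior for shared-covariance classes.
bayes_posterior <- function(x, means, sigma, priors) {
  d <- vapply(seq_len(nrow(means)), function(j) {
    v <- x - means[j, ]
    -0.5 * drop(v %*% solve(sigma, v)) + log(priors[j])
  }, numeric(1))
  e <- exp(d - max(d))
  e / sum(e)
}

# RMS helper.
rms <- function(x) sqrt(mean(x^2))

# Small default analysis config for fast tests: fewer surrogates, coarser
# grid bottom at 4 Hz (shorter supports).
fast_cfg <- function(...) {
  coherence_config(n_surrogates = 100L, ...)
}
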