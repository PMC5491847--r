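#' Configuration for wavelet coherence analysis
#'
#' @param omega0 Morlet center parameter (admissibility requires >= 5).
#' @param freqs evaluation grid in Hz; default 60 log-spaced points over
#'   2-60 Hz (about 12 voices per octave), covering the alpha (8-13 Hz) and
#'   beta (15-30 Hz) bands with margin.
#' @param n_surrogates Monte-Carlo surrogate pairs for the significance
#'   level (>= 100; default 300).
#' @param alpha_level nominal significance level (default 0.05).
#' @param time_smooth multiplier on the Gaussian time-smoothing sd
#'   (sd = `time_smooth` * scale / sqrt(2)).
#' @param scale_smooth_oct total width, in octaves, of the boxcar smoothing
#'   across scales (default 0.6).
#' @param occupancy fraction of in-cone time a frequency must spend above
#'   the significance threshold to count as significant in the global
#'   coherence (default 0.25).
#' @param rectify full-wave rectify EMG before demeaning in the muscle-pair
#'   helpers.  Off by default: the additive narrowband shared-drive model the
#'   generator (and filter) assume is read directly by raw-EMG coherence,
#'   while rectification demodulates a narrowband drive into a low-frequency
#'   envelope band.  Turn on to reproduce the classic
#'   rectified-intermuscular-coherence convention.
#' @param surrogate_model `"spectrum"` (default: surrogates share the
#'   data's own smoothed spectral shape, which keeps the null calibrated
#'   even for band-pass-filtered recordings), `"ar1"` (red-noise null with
#'   the data's lag-1 autocorrelation; reduces to white noise when that
#'   autocorrelation is 0), or `"white"`.
#' @param time_stride output time-grid stride of the coherence map in
#'   samples; `NULL` picks one that resolves the fastest scale analysed.
#' @return an object of class `coherence_config`.
#' @export
coherence_config <- function(omega0 = 6,
                             freqs = NULL,
                             n_surrogates = 300L,
                             alpha_level = 0.05,
                             time_smooth = 1,
                             scale_smooth_oct = 0.6,
                             occupancy = 0.25,
                             rectify = FALSE,
                             surrogate_model = c("spectrum", "ar1",
                                                 "white"),
                             time_stride = NULL) {
  if (omega0 < 5) stop("omega0 must be >= 5 for Morlet admissibility")
  if (is.null(freqs)) freqs <- 2 * 2^seq(0, log2(30), length.out = 60L)
  freqs <- sort(unique(as.numeric(freqs)))
  if (any(freqs <= 0)) stop("frequency grid must be positive")
  if (alpha_level <= 0 || alpha_level >= 1) stop("alpha_level must be in (0,1)")
  if (n_surrogates < 100L) {
    stop("n_surrogates must be >= 100 (quantile unstable below that)")
  }
  structure(
    list(omega0 = omega0, freqs = freqs,
         n_surrogates = as.integer(n_surrogates), alpha_level = alpha_level,
         time_smooth = time_smooth, scale_smooth_oct = scale_smooth_oct,
         occupancy = occupancy, rectify = isTRUE(rectify),
         surrogate_model = match.arg(surrogate_model),
         time_stride = time_stride),
    class = "coherence_config")
}

#' Wavelet coherence between two signals
#'
#' Time-frequency coherence: the magnitude-squared smoothed cross-wavelet
#' spectrum normalized by the smoothed auto-spectra, valued in `[0,1]`.
#' Smoothing (Gaussian in time at the wavelet's own scale, boxcar across
#' scales) is what makes the statistic informative; unsmoothed wavelet
#' coherence is identically 1.
#'
#' @param x,y numeric vectors of equal length.
#' @param fs sampling rate in Hz.
#' @param cfg a [coherence_config()].
#' @return an object of class `coherence_map` with fields `values`
#'   (frequency x time, in `[0,1]`), `freqs`, `times`, `coi` (per-time
#'   minimum reliable frequency in Hz) and `threshold` (`NULL` until set
#'   from [monte_carlo_threshold()]).
#' @export
wavelet_coherence <- function(x, y, fs, cfg = coherence_config()) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (all(x == 0) || all(y == 0)) {
    stop("coherence of an all-zero channel is undefined")
  }
  scales <- scale_for_freq(cfg$freqs, cfg$omega0)
  if (length(x) < 2 * sqrt(2) * max(scales) * fs) {
    stop(sprintf("signal too short for the %0.3g Hz band", min(cfg$freqs)))
  }
  eng <- cwt_coherence_engine(as.numeric(x), as.numeric(y), fs, cfg)
  structure(
    list(values = eng$values, freqs = eng$freqs, times = eng$times,
         coi = eng$coi, threshold = NULL, fs = fs, cfg = cfg),
    class = "coherence_map")
}

#' @export
print.coherence_map <- function(x, ...) {
  cat(sprintf(
    "<coherence_map> %d freqs (%.3g-%.3g Hz) x %d times (%.2f s)%s\n",
    length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
    max(x$times), if (is.null(x$threshold)) "" else ", threshold set"))
  invisible(x)
}

#' Logical in-cone mask of a coherence map
#'
#' @param map a `coherence_map`.
#' @return logical matrix (frequency x time), `TRUE` where the estimate is
#'   inside the cone of influence.
#' @export
in_coi <- function(map) {
  outer(map$freqs, map$coi, `>=`)
}

#' Monte-Carlo significance level for wavelet coherence
#'
#' For each grid frequency, the `1 - alpha_level` quantile of the coherence
#' statistic over `n_surrogates` independent surrogate pairs whose spectra
#' match the data channels under the configured null (the data's own
#' smoothed spectrum by default; an AR(1) red-noise or white alternative).
#' Surrogates are generated as circularly stationary Gaussian processes, so
#' every surrogate time point samples the null distribution.
#'
#' @param x,y the data channels (used for length and the AR(1) estimate).
#' @param fs sampling rate in Hz.
#' @param cfg a [coherence_config()].
#' @param seed integer seed; the threshold is deterministic given it.
#' @return numeric vector of per-frequency thresholds, strictly in (0,1).
#' @export
monte_carlo_threshold <- function(x, y, fs, cfg = coherence_config(),
                                  seed = 1L) {
  if (cfg$n_surrogates < 100L) stop("n_surrogates must be >= 100")
  with_seed(seed,
            mc_threshold_engine(as.numeric(x), as.numeric(y), fs, cfg))
}

#' Attach a significance threshold to a coherence map
#'
#' @param map a `coherence_map`.
#' @param threshold per-frequency threshold vector (values in (0,1)), e.g.
#'   from [monte_carlo_threshold()].
#' @return the map with `threshold` set.
#' @export
set_threshold <- function(map, threshold) {
  stopifnot(inherits(map, "coherence_map"))
  if (length(threshold) != length(map$freqs)) {
    stop("threshold must have one value per grid frequency")
  }
  if (any(threshold <= 0 | threshold >= 1)) {
    stop("thresholds must lie strictly in (0,1)")
  }
  map$threshold <- as.numeric(threshold)
  map
}

#' Global coherence: per-frequency aggregation of a map over time
#'
#' Aggregates the coherence map over the in-cone part of the record:
#' `power[f]` is the mean coherence over in-cone times, and a frequency is
#' significant when the fraction of in-cone time it spends above its
#' Monte-Carlo threshold exceeds the occupancy fraction (sustained, not
#' momentary, coupling).
#'
#' @param map a `coherence_map` with its threshold set.
#' @param occupancy occupancy fraction; defaults to the map's config value.
#' @return an object of class `global_coherence` with fields `freqs`,
#'   `power`, `significance`, `occupancy_frac` (observed exceedance
#'   fraction per frequency).
#' @export
global_coherence <- function(map, occupancy = NULL) {
  stopifnot(inherits(map, "coherence_map"))
  if (is.null(map$threshold)) {
    stop("set a significance threshold on the map first (see set_threshold)")
  }
  occupancy <- occupancy %||% map$cfg$occupancy
  mask <- in_coi(map)
  nf <- length(map$freqs)
  power <- occ <- numeric(nf)
  for (j in seq_len(nf)) {
    tj <- mask[j, ]
    if (!any(tj)) { power[j] <- NA_real_; occ[j] <- 0; next }
    v <- map$values[j, tj]
    power[j] <- mean(v)
    occ[j] <- mean(v > map$threshold[j])
  }
  structure(
    list(freqs = map$freqs, power = power, significance = occ > occupancy,
         occupancy_frac = occ, occupancy = occupancy),
    class = "global_coherence")
}

#' @export
print.global_coherence <- function(x, ...) {
  nsig <- sum(x$significance)
  cat(sprintf("<global_coherence> %d freqs, %d significant\n",
              length(x$freqs), nsig))
  invisible(x)
}

#' A contiguous frequency interval
#'
#' @param lo_hz,hi_hz band edges in Hz, `lo_hz <= hi_hz`; equality marks a
#'   "peak-only" band (a single significant grid point).
#' @return a one-row data.frame with columns `lo_hz`, `hi_hz`.
#' @export
frequency_band <- function(lo_hz, hi_hz = lo_hz) {
  if (any(lo_hz <= 0) || any(lo_hz > hi_hz)) {
    stop("need 0 < lo_hz <= hi_hz")
  }
  data.frame(lo_hz = as.numeric(lo_hz), hi_hz = as.numeric(hi_hz))
}

empty_bands <- function() data.frame(lo_hz = numeric(0), hi_hz = numeric(0))

#' Extract the significant frequency bands from a global coherence
#'
#' Maximal runs of consecutive significant grid frequencies become bands
#' `[lo, hi]`; single-point runs are returned as peak-only bands
#' (`lo == hi`).
#'
#' @param gc a `global_coherence`.
#' @param min_width_hz drop bands narrower than this (peak-only bands have
#'   width 0); default 0 keeps everything, leaving width decisions to
#'   [exclusion_rule()].
#' @return data.frame of bands (`lo_hz`, `hi_hz`), sorted by `lo_hz`.
#' @export
significant_bands <- function(gc, min_width_hz = 0) {
  stopifnot(inherits(gc, "global_coherence"))
  sig <- gc$significance
  if (!any(sig)) return(empty_bands())
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  bands <- data.frame(lo_hz = gc$freqs[starts[keep]],
                      hi_hz = gc$freqs[ends[keep]])
  bands[bands$hi_hz - bands$lo_hz >= min_width_hz, , drop = FALSE]
}

# EMG conditioning ahead of intermuscular coherence: optional full-wave
# rectification, demeaning, and a raised-cosine taper at the edges of every
# concatenated trial segment.  Cutting and joining trials creates step
# discontinuities that are time-locked across channels; untapered they
# masquerade as broadband low-frequency coupling.
condition_emg <- function(x, rectify = FALSE, boundaries = NULL, fs = NULL,
                          taper_s = 0.25) {
  if (rectify) x <- abs(x)
  x <- x - mean(x)
  if (!is.null(boundaries) && length(boundaries) > 2L && !is.null(fs)) {
    nr <- max(1L, round(taper_s * fs))
    ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = nr)))
    for (i in seq_len(length(boundaries) - 1L)) {
      a <- boundaries[i] + 1L
      b <- boundaries[i + 1L]
      k <- min(nr, floor((b - a + 1L) / 2))
      x[a:(a + k - 1L)] <- x[a:(a + k - 1L)] * ramp[seq_len(k)]
      x[(b - k + 1L):b] <- x[(b - k + 1L):b] * rev(ramp[seq_len(k)])
    }
  }
  x
}

#' Significant coherence bands of one muscle pair in one task signal
#'
#' Convenience wrapper running the whole per-pair analysis: EMG
#' conditioning (rectify + demean by default), wavelet coherence,
#' Monte-Carlo threshold, global coherence, band extraction.
#'
#' @param sig a `task_signal`.
#' @param ch_a,ch_b channel labels of the pair (e.g. `"FDS"`, `"mDEL"`).
#' @param cfg a [coherence_config()].
#' @param seed seed for the Monte-Carlo threshold.
#' @return list with `bands` (data.frame), `global` (`global_coherence`),
#'   and `map` (`coherence_map` with threshold set).
#' @export
pair_coherence_bands <- function(sig, ch_a, ch_b, cfg = coherence_config(),
                                 seed = 1L) {
  stopifnot(inherits(sig, "task_signal"))
  miss <- setdiff(c(ch_a, ch_b), sig$channels)
  if (length(miss)) stop("channel(s) not in signal: ",
                         paste(miss, collapse = ", "))
  x <- condition_emg(sig$samples[ch_a, ], cfg$rectify, sig$boundaries, sig$fs)
  y <- condition_emg(sig$samples[ch_b, ], cfg$rectify, sig$boundaries, sig$fs)
  map <- wavelet_coherence(x, y, sig$fs, cfg)
  thr <- monte_carlo_threshold(x, y, sig$fs, cfg, seed = seed)
  map <- set_threshold(map, thr)
  gc <- global_coherence(map)
  list(bands = significant_bands(gc), global = gc, map = map)
}
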