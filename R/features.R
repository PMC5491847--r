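# Hudgins time-domain feature extraction over sliding windows.
#
# Four features per channel per window: zero crossings (ZC), slope sign
# changes (SSC), mean absolute value (MAV), waveform length (WL).  ZC and
# SSC use an amplitude threshold epsilon to reject noise-level crossings.

#' Sliding-window specification
#'
#' Windows start every `step_ms` from the beginning of the signal; the
#' trailing windows truncate at the signal end, so the window count is
#' `ceil(n / step_samples)`.  With the 250/125 ms defaults, twelve 5-s
#' trials per task yield 480 windows per task (1,440 over the three hand
#' tasks), matching the dataset arithmetic of the protocol.
#'
#' @param window_ms window length in ms (default 250).
#' @param step_ms step between window starts in ms (default 125, i.e. 50%
#'   overlap).
#' @param epsilon amplitude threshold for ZC/SSC, in signal units; `NULL`
#'   (default) means 0.01 x the per-channel RMS of the signal being
#'   featurized.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(window_ms = 250, step_ms = 125, epsilon = NULL) {
  if (step_ms > window_ms) stop("step_ms must be <= window_ms")
  if (!is.null(epsilon) && any(epsilon < 0)) stop("epsilon must be >= 0")
  structure(list(window_ms = window_ms, step_ms = step_ms, epsilon = epsilon),
            class = "window_spec")
}

#' Sliding-window start/end indices
#'
#' @param n signal length in samples.
#' @param fs sampling rate in Hz.
#' @param spec a [window_spec()].
#' @return data.frame with 1-based inclusive `start`, `end` per window.
#' @export
sliding_windows <- function(n, fs, spec = window_spec()) {
  if (n < 1) stop("empty signal")
  step <- max(1L, round(spec$step_ms / 1000 * fs))
  win <- max(1L, round(spec$window_ms / 1000 * fs))
  starts <- seq(1L, n, by = step)
  data.frame(start = starts, end = pmin(starts + win - 1L, n))
}

#' Zero crossings of one window
#'
#' Counts adjacent sample pairs with opposite signs whose amplitude jump is
#' at least `epsilon`.
#'
#' @param x numeric window.
#' @param epsilon amplitude threshold.
#' @return integer count.
#' @export
zero_crossings <- function(x, epsilon = 0) {
  a <- x[-length(x)]; b <- x[-1]
  sum(a * b < 0 & abs(a - b) >= epsilon)
}

#' Slope sign changes of one window
#'
#' Counts interior local extrema (strictly greater or strictly smaller than
#' both neighbours) whose amplitude step to at least one neighbour reaches
#' `epsilon`.
#'
#' @param x numeric window (length >= 3).
#' @param epsilon amplitude threshold.
#' @return integer count.
#' @export
slope_sign_changes <- function(x, epsilon = 0) {
  if (length(x) < 3) return(0L)
  k <- 2:(length(x) - 1)
  ext <- (x[k] > x[k - 1] & x[k] > x[k + 1]) |
         (x[k] < x[k - 1] & x[k] < x[k + 1])
  jump <- pmax(abs(x[k] - x[k + 1]), abs(x[k] - x[k - 1])) >= epsilon
  sum(ext & jump)
}

#' Mean absolute value of one window
#' @param x numeric window.
#' @return mean of `|x|`.
#' @export
mean_absolute_value <- function(x) mean(abs(x))

#' Waveform length of one window
#' @param x numeric window (length >= 2).
#' @return sum of absolute first differences.
#' @export
waveform_length <- function(x) sum(abs(diff(x)))

FEATURE_NAMES <- c("ZC", "SSC", "MAV", "WL")

# Windowed feature extraction for one channel, vectorized via cumulative
# sums of the per-sample indicator/increment series.
channel_features <- function(x, wins, epsilon) {
  n <- length(x)
  a <- x[-n]; b <- x[-1]
  zc_i <- as.numeric(a * b < 0 & abs(a - b) >= epsilon)   # pair (k, k+1)
  k <- if (n >= 3) 2:(n - 1) else integer(0)
  ssc_i <- numeric(max(0L, n - 2L))
  if (length(k)) {
    ext <- (x[k] > x[k - 1] & x[k] > x[k + 1]) |
           (x[k] < x[k - 1] & x[k] < x[k + 1])
    jump <- pmax(abs(x[k] - x[k + 1]), abs(x[k] - x[k - 1])) >= epsilon
    ssc_i <- as.numeric(ext & jump)
  }
  abs_c <- c(0, cumsum(abs(x)))
  zc_c <- c(0, cumsum(zc_i))
  ssc_c <- c(0, cumsum(ssc_i))
  wl_c <- c(0, cumsum(abs(diff(x))))
  s <- wins$start; e <- wins$end
  len <- e - s + 1L
  # sample pairs (k, k+1) inside [s, e] are k = s .. e-1
  zc <- ifelse(e > s, zc_c[e] - zc_c[s], 0)
  # interior extrema k = s+1 .. e-1, stored at index k-1 of ssc_i
  ssc <- ifelse(e - s >= 2, ssc_c[e - 1L] - ssc_c[s], 0)
  mav <- (abs_c[e + 1L] - abs_c[s]) / len
  wl <- ifelse(e > s, wl_c[e] - wl_c[s], 0)
  cbind(ZC = zc, SSC = ssc, MAV = mav, WL = wl)
}

#' Extract Hudgins features from a task signal
#'
#' Slides the window over the concatenated signal and computes, per window
#' and channel, the four time-domain features in the fixed order ZC, SSC,
#' MAV, WL (channel blocks concatenated in channel order).  Each window is
#' labelled with the signal's task and the repetition its start sample
#' falls in.
#'
#' @param sig a `task_signal`.
#' @param spec a [window_spec()].
#' @param epsilon optional per-channel named epsilon vector overriding the
#'   spec rule (use one common scale across arms/tasks of an experiment).
#' @return object of class `window_features`: list with `X` (windows x
#'   features matrix), `y` (task labels), `groups` (data.frame task,
#'   loading, repetition per window), `channels`, `spec`.
#' @export
extract_features <- function(sig, spec = window_spec(), epsilon = NULL) {
  stopifnot(inherits(sig, "task_signal"))
  n <- ncol(sig$samples)
  wins <- sliding_windows(n, sig$fs, spec)
  if (is.null(epsilon)) {
    eps_by_ch <- spec$epsilon %||%
      (0.01 * apply(sig$samples, 1, function(v) sqrt(mean(v^2))))
    if (length(eps_by_ch) == 1L) {
      eps_by_ch <- stats::setNames(rep(eps_by_ch, length(sig$channels)),
                                   sig$channels)
    }
  } else {
    eps_by_ch <- epsilon
  }
  blocks <- lapply(sig$channels, function(ch) {
    channel_features(sig$samples[ch, ], wins, eps_by_ch[[ch]])
  })
  X <- do.call(cbind, blocks)
  colnames(X) <- as.vector(t(outer(sig$channels, FEATURE_NAMES, paste,
                                   sep = ".")))
  # repetition of each window = the trial its start sample falls in
  rep_of <- findInterval(wins$start - 1L, sig$boundaries,
                         rightmost.closed = FALSE)
  groups <- data.frame(
    task = sig$task, loading = sig$loading,
    repetition = sig$source_trials[pmin(rep_of, length(sig$source_trials))])
  structure(
    list(X = X, y = rep(sig$task, nrow(X)), groups = groups,
         channels = sig$channels, spec = spec, epsilon = eps_by_ch),
    class = "window_features")
}

#' Concatenate window feature sets
#' @param ... `window_features` objects with identical feature columns.
#' @return one combined `window_features`.
#' @export
bind_features <- function(...) {
  fs <- list(...)
  if (length(fs) == 1L && is.list(fs[[1]]) &&
      !inherits(fs[[1]], "window_features")) {
    fs <- fs[[1]]
  }
  stopifnot(all(vapply(fs, inherits, logical(1), "window_features")))
  structure(
    list(X = do.call(rbind, lapply(fs, `[[`, "X")),
         y = unlist(lapply(fs, `[[`, "y"), use.names = FALSE),
         groups = do.call(rbind, lapply(fs, `[[`, "groups")),
         channels = fs[[1]]$channels, spec = fs[[1]]$spec,
         epsilon = fs[[1]]$epsilon),
    class = "window_features")
}

#' @export
print.window_features <- function(x, ...) {
  cat(sprintf("<window_features> %d windows x %d features (%s)\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%s: %d", names(table(x$y)), table(x$y)),
                    collapse = ", ")))
  invisible(x)
}
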