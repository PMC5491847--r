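# Subject-specific, muscle-specific coherence-based band-stop filtering.
# Significant coherence bands between each distal muscle and the shoulder
# abductor (mDEL) are identified per task, merged across the three hand
# tasks, and turned into 4th-order Butterworth band-stop filters applied
# zero-phase per channel.

DISTAL_CHANNELS <- c("FCR", "FDS", "ECR", "EDC")

#' Merge significant frequency bands across tasks
#'
#' Interval union: overlapping or abutting bands coalesce; output sorted by
#' lower edge.
#'
#' @param per_task_bands list (typically named by task) of band data.frames
#'   (`lo_hz`, `hi_hz`).
#' @return one band data.frame, the union.
#' @export
merge_bands <- function(per_task_bands) {
  all_bands <- do.call(rbind, c(list(empty_bands()),
                                unname(per_task_bands)))
  if (!nrow(all_bands)) return(empty_bands())
  all_bands <- all_bands[order(all_bands$lo_hz, all_bands$hi_hz), ,
                         drop = FALSE]
  lo <- all_bands$lo_hz[1]; hi <- all_bands$hi_hz[1]
  out <- list()
  for (i in seq_len(nrow(all_bands))[-1]) {
    if (all_bands$lo_hz[i] <= hi + 1e-9) {   # abutting coalesce, fp-safe
      hi <- max(hi, all_bands$hi_hz[i])
    } else {
      out[[length(out) + 1L]] <- c(lo, hi)
      lo <- all_bands$lo_hz[i]; hi <- all_bands$hi_hz[i]
    }
  }
  out[[length(out) + 1L]] <- c(lo, hi)
  m <- do.call(rbind, out)
  data.frame(lo_hz = m[, 1], hi_hz = m[, 2])
}

#' Is a merged band set eligible for filtering?
#'
#' Subjects whose merged coherence is empty, or consists only of isolated
#' peaks (bands narrower than `min_width_hz`; a peak-only band has width 0),
#' receive no coherence filter and are flagged for exclusion from the
#' before/after comparison.
#'
#' @param merged band data.frame from [merge_bands()].
#' @param min_width_hz minimum band width that counts as a real range; the
#'   natural choice is one step of the analysis frequency grid.
#' @return `TRUE` if at least one band is at least `min_width_hz` wide.
#' @export
exclusion_rule <- function(merged, min_width_hz = 0.1) {
  if (!nrow(merged)) return(FALSE)
  any(merged$hi_hz - merged$lo_hz >= min_width_hz)
}

# Butterworth band-stop in zeros-poles-gain form, returned as a cascade of
# real biquads.  Designed analytically (analog prototype poles, analog
# low-pass -> band-stop transform, bilinear transform with prewarped edges)
# because a transfer-function-form design collapses numerically for the
# narrow normalized bands (a few Hz at 1 kHz) this method routinely
# produces.
butter_bandstop_sos <- function(lo_hz, hi_hz, fs, order = 4L) {
  w1 <- 2 * fs * tan(pi * lo_hz / fs)      # prewarped analog edges
  w2 <- 2 * fs * tan(pi * hi_hz / fs)
  w0 <- sqrt(w1 * w2); bw <- w2 - w1
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # Re < 0
  # each prototype pole p solves  bw*s / (s^2 + w0^2) = p
  poles <- unlist(lapply(proto, function(p) {
    d <- sqrt(as.complex(bw^2 - 4 * p^2 * w0^2))
    c((bw + d) / (2 * p), (bw - d) / (2 * p))
  }))
  zeros <- rep(c(1i * w0, -1i * w0), order)
  zp <- (2 * fs + poles) / (2 * fs - poles)   # bilinear
  zz <- (2 * fs + zeros) / (2 * fs - zeros)
  gain <- Re(prod(1 - zp) / prod(1 - zz))     # unit gain at DC
  # pair conjugates into real biquads
  up <- zp[Im(zp) > 0][order(Arg(zp[Im(zp) > 0]))]
  uz <- zz[Im(zz) > 0]
  sos <- lapply(seq_len(order), function(i) {
    p <- up[i]; z <- uz[i]
    list(b = c(1, -2 * Re(z), Mod(z)^2), a = c(1, -2 * Re(p), Mod(p)^2))
  })
  sos[[1]]$b <- sos[[1]]$b * gain
  if (any(Mod(up) >= 1)) {
    stop(sprintf("unstable band-stop design for [%.3g, %.3g] Hz",
                 lo_hz, hi_hz))
  }
  sos
}

#' Design a cascade of 4th-order Butterworth band-stop filters
#'
#' One order-4 band-stop per band (8 poles after the band transformation),
#' realized as second-order sections and applied in cascade.  Bands
#' narrower than `min_stop_width_hz` are padded symmetrically to that width
#' before design (very narrow IIR notches are numerically fragile).
#' Stability of every section is verified (all poles strictly inside the
#' unit circle).
#'
#' @param bands band data.frame (`lo_hz`, `hi_hz`).
#' @param fs sampling rate in Hz.
#' @param order Butterworth prototype order per band (default 4).
#' @param min_stop_width_hz minimum designed stop width (default 2 Hz).
#' @return list of class `bandstop_cascade`: one element per band with its
#'   second-order sections and the (possibly padded) band; an empty list is
#'   the identity filter.
#' @export
design_bandstop <- function(bands, fs, order = 4L, min_stop_width_hz = 2) {
  stages <- lapply(seq_len(nrow(bands)), function(i) {
    lo <- bands$lo_hz[i]; hi <- bands$hi_hz[i]
    w <- hi - lo
    if (w < min_stop_width_hz) {
      pad <- (min_stop_width_hz - w) / 2
      lo <- lo - pad; hi <- hi + pad
    }
    if (lo <= 0 || hi >= fs / 2) {
      stop(sprintf("stop band [%.3g, %.3g] Hz touches 0 or Nyquist", lo, hi))
    }
    list(sos = butter_bandstop_sos(lo, hi, fs, order), lo_hz = lo,
         hi_hz = hi)
  })
  structure(stages, class = "bandstop_cascade", fs = fs, order = order)
}

# Frequency response (complex) of a band-stop cascade at freqs f (Hz).
cascade_response <- function(cascade, f, fs) {
  z <- exp(-2i * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (st in cascade) {
    for (s2 in st$sos) {
      h <- h * (s2$b[1] + s2$b[2] * z + s2$b[3] * z^2) /
        (s2$a[1] + s2$a[2] * z + s2$a[3] * z^2)
    }
  }
  h
}

# Zero-phase application of a band-stop cascade to one channel.
apply_cascade <- function(x, cascade) {
  for (st in cascade) {
    for (s2 in st$sos) {
      x <- signal::filtfilt(signal::Arma(b = s2$b, a = s2$a), x)
    }
  }
  if (anyNA(x)) stop("band-stop filtering produced NaNs (unstable design?)")
  x
}

#' Per-subject, per-loading bank of coherence-based band-stop filters
#'
#' @param stop_bands named list: channel -> band data.frame.
#' @param fs sampling rate in Hz.
#' @param subject_id,loading identifiers.
#' @param eligible result of the subject-level [exclusion_rule()]; an
#'   ineligible bank passes signals through unchanged.
#' @param order Butterworth order (default 4).
#' @return an object of class `filter_bank`.
#' @export
filter_bank <- function(stop_bands, fs, subject_id = NA_character_,
                        loading = NA_character_, eligible = TRUE,
                        order = 4L) {
  cascades <- lapply(stop_bands, function(b) {
    if (is.null(b) || !nrow(b)) NULL else design_bandstop(b, fs, order)
  })
  structure(
    list(subject_id = subject_id, loading = loading, fs = fs, order = order,
         stop_bands = stop_bands, cascades = cascades,
         applied_channels = names(stop_bands)[
           !vapply(cascades, is.null, logical(1))],
         eligible = isTRUE(eligible)),
    class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> subject %s, loading %s, %seligible\n",
              x$subject_id, x$loading, if (x$eligible) "" else "NOT "))
  for (ch in names(x$stop_bands)) {
    b <- x$stop_bands[[ch]]
    cat(sprintf("  %s: %s\n", ch, if (is.null(b) || !nrow(b)) "-" else {
      paste(sprintf("[%.1f, %.1f] Hz", b$lo_hz, b$hi_hz), collapse = ", ")
    }))
  }
  invisible(x)
}

#' Apply a filter bank to a task signal
#'
#' Each channel with stop bands is filtered zero-phase through its band-stop
#' cascade; channels without bands (and every channel of an ineligible
#' bank) pass through bit-identically.  Length is preserved.
#'
#' @param sig a `task_signal`.
#' @param bank a `filter_bank`.
#' @return the filtered `task_signal`.
#' @export
apply_filterbank <- function(sig, bank) {
  stopifnot(inherits(sig, "task_signal"), inherits(bank, "filter_bank"))
  miss <- setdiff(bank$applied_channels, sig$channels)
  if (length(miss)) {
    stop("bank channels missing from signal: ", paste(miss, collapse = ", "))
  }
  if (!bank$eligible) return(sig)
  out <- sig
  for (ch in bank$applied_channels) {
    out$samples[ch, ] <- apply_cascade(sig$samples[ch, ],
                                       bank$cascades[[ch]])
  }
  out
}

#' Build the coherence-based filter banks of one subject
#'
#' For each loading present in the recording and each distal channel (FCR,
#' FDS, ECR, EDC), identifies the frequency ranges of significant wavelet
#' coherence with mDEL in each of the three hand tasks, merges them across
#' tasks, and designs the per-channel band-stop cascade.  The subject-level
#' exclusion rule fires when no channel carries a band wider than one
#' frequency-grid step: such subjects get a pass-through bank flagged
#' ineligible.  mDEL itself is never filtered (the synergy-induced
#' component is defined at the wrist/fingers).
#'
#' @param rec an `emg_recording` containing all three tasks per loading.
#' @param cfg a [coherence_config()].
#' @param loadings loadings to build banks for; default all loadings present
#'   in the annotations.
#' @param seed master seed for the Monte-Carlo thresholds.
#' @param subject_id identifier stored in the banks.
#' @param reference_channel proximal channel of every coherence pair.
#' @param channels distal channels to analyse/filter.
#' @param min_freq_hz lowest frequency searched for significant bands
#'   (default 5 Hz, the conventional EMG acquisition high-pass corner).
#'   Below the acquisition band the recording carries no physiological
#'   signal, so coherence there is uninterpretable.
#' @return named list: loading -> `filter_bank`, with attribute `detail`
#'   (per loading/channel/task band tables) for logging.
#' @export
build_subject_filters <- function(rec, cfg = coherence_config(),
                                  loadings = NULL, seed = 1L,
                                  subject_id = "S1",
                                  reference_channel = "mDEL",
                                  channels = DISTAL_CHANNELS,
                                  min_freq_hz = 5) {
  validate_recording(rec)
  cfg$freqs <- cfg$freqs[cfg$freqs >= min_freq_hz]
  if (length(cfg$freqs) < 10L) stop("min_freq_hz leaves too few grid points")
  ann <- rec$annotations
  loadings <- loadings %||% intersect(LOADINGS, unique(ann$loading))
  grid_step <- min(diff(cfg$freqs))
  banks <- list()
  detail <- list()
  for (ld in loadings) {
    have <- unique(ann$task[ann$loading == ld])
    if (!all(TASKS %in% have)) {
      stop(sprintf("loading '%s' lacks task(s): %s", ld,
                   paste(setdiff(TASKS, have), collapse = ", ")))
    }
    sigs <- lapply(stats::setNames(TASKS, TASKS), function(tk) {
      segment_concatenate(rec, tk, ld)
    })
    stop_bands <- list()
    for (ch in channels) {
      per_task <- lapply(sigs, function(ts) {
        pair_coherence_bands(
          ts, ch, reference_channel, cfg,
          seed = derive_seed(seed, subject_id, ld, ch, ts$task))$bands
      })
      stop_bands[[ch]] <- merge_bands(per_task)
      detail[[paste(ld, ch, sep = ".")]] <- per_task
    }
    eligible <- any(vapply(stop_bands, exclusion_rule, logical(1),
                           min_width_hz = grid_step))
    keep <- if (eligible) {
      lapply(stop_bands, function(b) {
        b[b$hi_hz - b$lo_hz >= grid_step, , drop = FALSE]
      })
    } else {
      lapply(stop_bands, function(b) empty_bands())
    }
    banks[[ld]] <- filter_bank(keep, fs = rec$fs, subject_id = subject_id,
                               loading = ld, eligible = eligible)
  }
  attr(banks, "detail") <- detail
  banks
}
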