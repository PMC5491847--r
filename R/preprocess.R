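#' Zero-phase band-pass preconditioning of a recording
#'
#' Applies a 4th-order Butterworth band-pass (default 5-450 Hz, the
#' conventional surface-EMG acquisition band) forward and backward to every
#' channel.  Zero-phase application is appropriate because all processing
#' here is offline; it squares the magnitude response, so single-pass -3 dB
#' corners become -6 dB.
#'
#' @param rec an `emg_recording`.
#' @param lo_hz,hi_hz band edges in Hz; `hi_hz` must be below Nyquist.
#' @param order Butterworth prototype order (default 4).
#' @return a new `emg_recording` with filtered samples; annotations unchanged.
#' @export
bandpass_preprocess <- function(rec, lo_hz = 5, hi_hz = 450, order = 4L) {
  validate_recording(rec)
  nyq <- rec$fs / 2
  if (hi_hz >= nyq) {
    stop(sprintf("hi_hz = %g must be below the Nyquist frequency %g Hz",
                 hi_hz, nyq))
  }
  if (lo_hz <= 0 || lo_hz >= hi_hz) stop("need 0 < lo_hz < hi_hz")
  bf <- signal::butter(order, c(lo_hz, hi_hz) / nyq, type = "pass")
  out <- rec
  for (i in seq_len(nrow(rec$samples))) {
    out$samples[i, ] <- signal::filtfilt(bf, rec$samples[i, ])
  }
  out
}

#' Concatenate the task-phase EMG of one (task, loading) cell
#'
#' Extracts every annotated interval matching `task` and `loading`, in
#' repetition order, and concatenates them into one `task_signal`, dropping
#' the idling samples between trials.  The output length is exactly the sum
#' of the matched interval lengths.
#'
#' @param rec an `emg_recording`.
#' @param task one of `relax`, `open`, `grasp`.
#' @param loading one of `table`, `sabd25`, `sabd50`.
#' @return a `task_signal`.
#' @export
segment_concatenate <- function(rec, task, loading) {
  validate_recording(rec)
  task <- match.arg(task, TASKS)
  loading <- match.arg(loading, LOADINGS)
  ann <- rec$annotations
  sel <- ann[ann$task == task & ann$loading == loading, , drop = FALSE]
  if (!nrow(sel)) {
    stop(sprintf("no annotations for task '%s' at loading '%s'",
                 task, loading))
  }
  sel <- sel[order(sel$repetition), , drop = FALSE]
  pieces <- lapply(seq_len(nrow(sel)), function(i) {
    rec$samples[, (sel$start_sample[i] + 1L):sel$end_sample[i], drop = FALSE]
  })
  lens <- vapply(pieces, ncol, integer(1))
  task_signal(do.call(cbind, pieces), fs = rec$fs, channels = rec$channels,
              task = task, loading = loading,
              source_trials = sel$repetition,
              boundaries = c(0L, cumsum(lens)))
}
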