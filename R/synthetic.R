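# Synthetic surface-EMG generator with a loading-dependent shared alpha-band
# synergy drive.  The generative model (per channel): a Gaussian broadband
# carrier band-limited to 20-400 Hz, amplitude-modulated by a trapezoidal
# task envelope, plus additive narrowband shared drives -- one alpha-band
# (8-13 Hz) "synergy" process common to mDEL and the wrist/finger flexors
# whose gain grows with shoulder-abduction loading, and one weaker beta-band
# (15-30 Hz) "voluntary" process common to the voluntarily active channels.
# Shared processes are what create intermuscular coherence in their bands.

#' Subject profile for the synthetic EMG generator
#'
#' Describes one simulated subject: where the synergy drive projects, how
#' strongly it scales with shoulder-abduction loading, and how severe the
#' impairment is.  `severity` multiplies the synergy gain, so `severity = 0`
#' is an able-bodied control.
#'
#' @param synergy_band alpha-band interval (Hz) of the shared synergy drive.
#' @param voluntary_band beta-band interval (Hz) of the shared voluntary
#'   drive.
#' @param synergy_gain named numeric: coupling amplitude (in carrier-sd
#'   units) per loading, monotone non-decreasing from `table` to `sabd50`.
#' @param synergy_targets channels receiving the shared synergy drive.
#' @param synergy_task_gain named numeric multiplier of the synergy
#'   amplitude per task (default 1 for all tasks: the involuntary drive
#'   depends on the shoulder load, not on the hand intent).
#' @param synergy_burst depth of the slow (0.3-1.5 Hz) shared amplitude
#'   modulation of the synergy drive.  The involuntary drive waxes and
#'   wanes within a trial, so individual 250-ms windows see very different
#'   synergy levels -- the heavy-tailed amplitude noise that corrupts the
#'   amplitude-coded features the classifier relies on.
#' @param synergy_jitter length-2 range of the uniform per-trial multiplier
#'   on the synergy amplitude.  The involuntary drive fluctuates from trial
#'   to trial; that fluctuation, not the mean level, is what confuses the
#'   classifier (a constant offset would simply be absorbed into the class
#'   means).
#' @param voluntary_gain amplitude of the shared beta drive on voluntarily
#'   active channels.
#' @param carrier_noise_sd named numeric, broadband carrier sd per channel.
#' @param baseline_noise_sd sd of the independent white sensor-noise floor,
#'   in carrier-sd units (electrode/amplifier noise present in any real
#'   recording; also what keeps coherence well-defined outside the carrier
#'   band).
#' @param active_level envelope multiplier of a voluntarily active channel
#'   relative to its resting level.
#' @param activation_jitter length-2 range of the uniform per-trial
#'   multiplier on `active_level`: paretic voluntary effort fluctuates from
#'   trial to trial, so some maximal-effort trials barely exceed rest.
#' @param severity scalar in `[0,1]` scaling the synergy gain.
#' @param subject_id identifier carried into reports.
#' @return an object of class `subject_profile`.
#' @export
subject_profile <- function(synergy_band = c(8, 13),
                            voluntary_band = c(15, 30),
                            synergy_gain = c(table = 0, sabd25 = 2.5,
                                             sabd50 = 5),
                            synergy_targets = c("mDEL", "FCR", "FDS"),
                            synergy_task_gain = c(relax = 1, open = 1,
                                                  grasp = 1),
                            synergy_jitter = c(0.2, 1.8),
                            synergy_burst = 0.6,
                            voluntary_gain = 0.3,
                            carrier_noise_sd = NULL,
                            baseline_noise_sd = 0.15,
                            active_level = 3,
                            activation_jitter = c(0.25, 1.2),
                            severity = 1,
                            subject_id = "S1") {
  if (is.null(carrier_noise_sd)) {
    carrier_noise_sd <- stats::setNames(rep(1, length(DEFAULT_CHANNELS)),
                                        DEFAULT_CHANNELS)
  }
  stopifnot(length(synergy_band) == 2, synergy_band[1] < synergy_band[2],
            length(voluntary_band) == 2, voluntary_band[1] < voluntary_band[2])
  if (any(synergy_gain < 0) || any(voluntary_gain < 0)) {
    stop("gains must be >= 0")
  }
  sg <- synergy_gain[LOADINGS]
  if (any(is.na(sg))) stop("synergy_gain must name all loadings")
  if (any(diff(sg) < 0)) {
    stop("synergy_gain must be monotone non-decreasing in loading")
  }
  if (severity < 0 || severity > 1) stop("severity must lie in [0,1]")
  structure(
    list(synergy_band = as.numeric(synergy_band),
         voluntary_band = as.numeric(voluntary_band),
         synergy_gain = sg, synergy_targets = synergy_targets,
         synergy_task_gain = synergy_task_gain[TASKS],
         synergy_jitter = as.numeric(synergy_jitter),
         synergy_burst = synergy_burst,
         voluntary_gain = voluntary_gain,
         carrier_noise_sd = carrier_noise_sd,
         baseline_noise_sd = baseline_noise_sd,
         active_level = active_level,
         activation_jitter = as.numeric(activation_jitter),
         severity = severity, subject_id = subject_id),
    class = "subject_profile")
}

#' Protocol of a simulated recording session
#'
#' @param tasks tasks to record (default all three hand tasks).
#' @param loadings loading levels to record.
#' @param repetitions trials per (task, loading) cell.
#' @param trial_duration_s task-phase duration per trial in seconds.
#' @param gap_s idle gap inserted between trials (excluded by annotations).
#' @param fs sampling rate in Hz.
#' @param seed master seed of the session.
#' @return an object of class `protocol_spec`.
#' @export
protocol_spec <- function(tasks = TASKS, loadings = c("sabd25", "sabd50"),
                          repetitions = 12L, trial_duration_s = 5,
                          gap_s = 0.5, fs = 1000, seed = 1L) {
  tasks <- match.arg(tasks, TASKS, several.ok = TRUE)
  loadings <- match.arg(loadings, LOADINGS, several.ok = TRUE)
  if (repetitions < 1L) stop("repetitions must be >= 1")
  if (trial_duration_s <= 0) stop("trial_duration_s must be > 0")
  structure(
    list(tasks = tasks, loadings = loadings,
         repetitions = as.integer(repetitions),
         trial_duration_s = trial_duration_s, gap_s = gap_s,
         fs = fs, seed = as.integer(seed)),
    class = "protocol_spec")
}

# Which channels are voluntarily active in a task; mDEL is active whenever
# the arm is lifted (any sabd loading).
active_channels <- function(task, loading) {
  act <- switch(task,
                grasp = c("FCR", "FDS"),
                open = c("ECR", "EDC"),
                relax = character(0))
  if (loading != "table") act <- c("mDEL", act)
  act
}

# Trapezoidal activation envelope: rises from `rest` to `level` over
# `rise_s`, holds, and falls back over the last `rise_s`.
task_envelope <- function(n, fs, level, rest = 1, rise_s = 0.25) {
  nr <- max(1L, min(round(rise_s * fs), floor(n / 2)))
  env <- rep(level, n)
  ramp <- seq(0, 1, length.out = nr)
  env[seq_len(nr)] <- rest + (level - rest) * ramp
  env[(n - nr + 1L):n] <- rest + (level - rest) * rev(ramp)
  env
}

# Raised-cosine taper from 0 to 1 over `rise_s` at both ends.
drive_taper <- function(n, fs, rise_s = 0.25) {
  nr <- max(1L, min(round(rise_s * fs), floor(n / 2)))
  ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = nr)))
  tp <- rep(1, n)
  tp[seq_len(nr)] <- ramp
  tp[(n - nr + 1L):n] <- rev(ramp)
  tp
}

# White noise band-limited with a zero-phase 4th-order Butterworth
# band-pass, scaled to unit RMS.
narrowband_noise <- function(n, fs, band) {
  bf <- signal::butter(4, pmin(band / (fs / 2), 0.999), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n + 2000L))[1001L:(1000L + n)]
  x / max(sd(x), .Machine$double.eps)
}

#' Generate one synthetic task-phase trial
#'
#' Builds a channels x time matrix: per-channel broadband carriers (20-400
#' Hz Gaussian noise) amplitude-modulated by trapezoidal task envelopes
#' (grasp activates the flexors FCR/FDS, open the extensors ECR/EDC, relax
#' leaves everything at rest; mDEL is active whenever the arm is lifted),
#' plus one shared alpha-band synergy process added to the synergy target
#' channels with gain `severity * synergy_gain[loading]`, and one shared
#' beta-band process added to the voluntarily active channels.  The synergy
#' drive is present in every task, including relax: involuntary distal
#' activity appears whenever the shoulder abductor is loaded.
#'
#' @param profile a [subject_profile()].
#' @param task,loading cell to simulate.
#' @param duration_s trial duration in seconds.
#' @param fs sampling rate in Hz.
#' @param seed integer; output is deterministic given it.
#' @return a `task_signal` with one source trial.
#' @export
generate_trial <- function(profile, task, loading, duration_s = 5,
                           fs = 1000, seed = 1L) {
  stopifnot(inherits(profile, "subject_profile"))
  task <- match.arg(task, TASKS)
  loading <- match.arg(loading, LOADINGS)
  channels <- names(profile$carrier_noise_sd)
  n <- round(duration_s * fs)
  with_seed(seed, {
    act <- active_channels(task, loading)
    level_trial <- profile$active_level *
      runif(1, profile$activation_jitter[1], profile$activation_jitter[2])
    X <- matrix(0, length(channels), n, dimnames = list(channels, NULL))
    for (ch in channels) {
      level <- if (ch %in% act) max(1, level_trial) else 1
      env <- task_envelope(n, fs, level)
      X[ch, ] <- profile$carrier_noise_sd[[ch]] *
        (env * narrowband_noise(n, fs, c(20, 400)) +
           profile$baseline_noise_sd * rnorm(n))
    }
    # shared drives taper in/out over 250 ms so trial concatenation has no
    # step discontinuities (which would masquerade as broadband coupling)
    taper <- drive_taper(n, fs)
    syn_amp <- profile$severity * profile$synergy_gain[[loading]] *
      profile$synergy_task_gain[[task]] *
      runif(1, profile$synergy_jitter[1], profile$synergy_jitter[2])
    if (syn_amp > 0) {
      drive <- narrowband_noise(n, fs, profile$synergy_band) * taper
      if (profile$synergy_burst > 0) {
        burst <- pmax(0.05, 1 + profile$synergy_burst *
                        narrowband_noise(n, fs, c(0.3, 1.5)))
        drive <- drive * burst
      }
      for (ch in intersect(profile$synergy_targets, channels)) {
        X[ch, ] <- X[ch, ] + syn_amp * drive
      }
    }
    # the corticospinal beta drive is shared among the distal task muscles;
    # mDEL, when active, carries its own independent beta process (the
    # shoulder is driven by a different corticospinal population)
    if (profile$voluntary_gain > 0 && length(act)) {
      act_dist <- intersect(setdiff(act, "mDEL"), channels)
      if (length(act_dist)) {
        beta <- narrowband_noise(n, fs, profile$voluntary_band) * taper
        for (ch in act_dist) {
          X[ch, ] <- X[ch, ] + profile$voluntary_gain * beta
        }
      }
      if ("mDEL" %in% act && "mDEL" %in% channels) {
        X["mDEL", ] <- X["mDEL", ] + profile$voluntary_gain *
          narrowband_noise(n, fs, profile$voluntary_band) * taper
      }
    }
    task_signal(X, fs = fs, channels = channels, task = task,
                loading = loading, source_trials = 1L)
  })
}

#' Generate a full annotated session for one subject
#'
#' Simulates every (task, loading, repetition) cell of the protocol, in
#' randomized trial order (as in the experimental protocol), separated by
#' idle gaps, and returns an annotated [emg_recording()].  Each trial draws
#' its own RNG substream derived from `(seed, task, loading, repetition)`,
#' so any single trial can be regenerated independently.
#'
#' @param profile a [subject_profile()].
#' @param protocol a [protocol_spec()].
#' @return an `emg_recording` with one annotation per trial.
#' @export
generate_session <- function(profile, protocol) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(protocol, "protocol_spec"))
  fs <- protocol$fs
  cells <- expand.grid(repetition = seq_len(protocol$repetitions),
                       task = protocol$tasks, loading = protocol$loadings,
                       stringsAsFactors = FALSE)
  ord <- with_seed(derive_seed(protocol$seed, "order"),
                   sample.int(nrow(cells)))
  cells <- cells[ord, , drop = FALSE]
  n_trial <- round(protocol$trial_duration_s * fs)
  n_gap <- round(protocol$gap_s * fs)
  channels <- names(profile$carrier_noise_sd)
  total <- nrow(cells) * (n_trial + n_gap) + n_gap
  X <- matrix(0, length(channels), total, dimnames = list(channels, NULL))
  ann <- vector("list", nrow(cells))
  pos <- n_gap
  for (i in seq_len(nrow(cells))) {
    tr <- generate_trial(
      profile, cells$task[i], cells$loading[i], protocol$trial_duration_s,
      fs, seed = derive_seed(protocol$seed, profile$subject_id,
                             cells$task[i], cells$loading[i],
                             cells$repetition[i]))
    X[, (pos + 1L):(pos + n_trial)] <- tr$samples
    ann[[i]] <- data.frame(start_sample = pos, end_sample = pos + n_trial,
                           task = cells$task[i], loading = cells$loading[i],
                           repetition = cells$repetition[i],
                           stringsAsFactors = FALSE)
    pos <- pos + n_trial + n_gap
  }
  emg_recording(X, fs = fs, channels = channels,
                annotations = do.call(rbind, ann))
}

#' Simulate a cohort of subject profiles
#'
#' Draws `n_subjects` profiles with severities spread over `severity_range`
#' and a per-subject jitter of the synergy band center (no two subjects
#' share the same significant band, mirroring the between-subject variation
#' seen clinically).
#'
#' @param n_subjects number of subjects.
#' @param severity_range length-2 numeric in `[0,1]`.
#' @param seed integer seed.
#' @param ... passed on to [subject_profile()].
#' @return list of `subject_profile`s with ids `S1..Sn`.
#' @export
make_cohort <- function(n_subjects, severity_range = c(0.3, 1), seed = 1L,
                        ...) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  if (length(severity_range) != 2 || any(severity_range < 0) ||
      any(severity_range > 1) || severity_range[1] > severity_range[2]) {
    stop("severity_range must be an increasing pair within [0,1]")
  }
  with_seed(seed, {
    sev <- if (n_subjects == 1L) mean(severity_range) else {
      seq(severity_range[1], severity_range[2], length.out = n_subjects)
    }
    lapply(seq_len(n_subjects), function(i) {
      shift <- runif(1, -1.5, 1.5)
      width <- runif(1, 3.5, 5)
      center <- 10.5 + shift
      subject_profile(
        synergy_band = c(center - width / 2, center + width / 2),
        severity = sev[i], subject_id = sprintf("S%d", i), ...)
    })
  })
}
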