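# The before/after-filter experiment: for each subject and loading, the
# same segmentation -> windowing -> Hudgins features -> LDA pipeline is run
# twice, once on the preprocessed EMG and once after the subject-specific
# coherence-based band-stop filters, with an identical repetition-level
# train/test split, so the paired accuracy difference isolates the filter.

#' Experiment configuration for the before/after comparison
#'
#' @param coherence a [coherence_config()].
#' @param windows a [window_spec()].
#' @param train_frac training fraction of repetitions (default 0.75).
#' @param cv_k cross-validation folds for the shrinkage search (default 10,
#'   capped at the per-task repetition count of the training set).
#' @param shrinkage_grid candidate shrinkage values for the LDA.
#' @param bandpass length-2 acquisition band-pass in Hz applied to every
#'   recording before analysis.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(coherence = coherence_config(),
                              windows = window_spec(),
                              train_frac = 0.75, cv_k = 10L,
                              shrinkage_grid = c(0, 1e-4, 1e-3, 1e-2, 1e-1),
                              bandpass = c(5, 450)) {
  structure(
    list(coherence = coherence, windows = windows, train_frac = train_frac,
         cv_k = as.integer(cv_k), shrinkage_grid = shrinkage_grid,
         bandpass = bandpass),
    class = "experiment_config")
}

# One classification arm: features per task, shared split, CV-selected
# shrinkage, evaluation on the held-out repetitions.
classify_arm <- function(sigs, cfg, seed) {
  feats <- bind_features(lapply(sigs, extract_features, spec = cfg$windows))
  sp <- split_train_test(feats, cfg$train_frac, seed = seed)
  cv <- cross_validate(sp$train, k = cfg$cv_k,
                       shrinkage_grid = cfg$shrinkage_grid, seed = seed)
  fit <- lda_fit(sp$train, cv$shrinkage)
  list(report = evaluate(fit, sp$test), cv = cv, model = fit,
       split = sp$assignment, n_windows = nrow(feats$X))
}

#' Run the before/after-filter experiment for one subject and loading
#'
#' Preprocesses the recording (acquisition band-pass), concatenates the
#' three task signals at `loading`, classifies them without the coherence
#' filter, builds the subject's filter bank from the significant
#' mDEL-to-distal coherence bands, and (if the subject is filter-eligible)
#' classifies the filtered signals with the identical train/test split.
#' Ineligible subjects pass through unfiltered: their "with" arm equals
#' their "without" arm and they are flagged excluded.
#'
#' @param rec an `emg_recording` with all three tasks at `loading`.
#' @param loading loading level to analyse.
#' @param cfg an [experiment_config()].
#' @param seed integer master seed (split, CV folds, Monte-Carlo
#'   thresholds).
#' @param subject_id identifier for reports.
#' @return object of class `subject_result`: `without`, `with`
#'   (`eval_report`s), `bank` (`filter_bank`), `excluded` (logical),
#'   `improvement` (percentage points, `NA` when excluded), plus the CV
#'   records of both arms.
#' @export
run_subject <- function(rec, loading, cfg = experiment_config(), seed = 1L,
                        subject_id = "S1") {
  validate_recording(rec)
  rec <- bandpass_preprocess(rec, cfg$bandpass[1], cfg$bandpass[2])
  sigs <- lapply(stats::setNames(TASKS, TASKS), function(tk) {
    segment_concatenate(rec, tk, loading)
  })
  without <- classify_arm(sigs, cfg, seed)
  banks <- build_subject_filters(rec, cfg$coherence, loadings = loading,
                                 seed = seed, subject_id = subject_id,
                                 min_freq_hz = cfg$bandpass[1])
  bank <- banks[[loading]]
  if (bank$eligible) {
    fsigs <- lapply(sigs, apply_filterbank, bank = bank)
    with_arm <- classify_arm(fsigs, cfg, seed)
    stopifnot(identical(without$split, with_arm$split))
  } else {
    with_arm <- without
  }
  improvement <- if (bank$eligible) {
    with_arm$report$overall_accuracy - without$report$overall_accuracy
  } else NA_real_
  structure(
    list(subject_id = subject_id, loading = loading,
         without = without$report, with = with_arm$report, bank = bank,
         excluded = !bank$eligible, improvement = improvement,
         cv_without = without$cv, cv_with = with_arm$cv,
         split = without$split, n_windows = without$n_windows),
    class = "subject_result")
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf(
    "<subject_result> %s @ %s: without %.1f%%, with %.1f%%, %s\n",
    x$subject_id, x$loading, x$without$overall_accuracy,
    x$with$overall_accuracy,
    if (x$excluded) "EXCLUDED (no filter applied)" else {
      sprintf("improvement %+.1f pp", x$improvement)
    }))
  invisible(x)
}

#' Run the full cohort experiment
#'
#' Generates (or accepts) one session per subject, runs
#' [run_subject()] for every requested loading, and summarizes the paired
#' improvement across the non-excluded subjects (mean +/- SE per loading).
#'
#' @param profiles list of [subject_profile()]s (e.g. from
#'   [make_cohort()]), or `NULL` if `recordings` are given.
#' @param protocol a [protocol_spec()] used for every subject (its seed is
#'   combined with the subject id).
#' @param cfg an [experiment_config()].
#' @param loadings loadings to analyse (default: the protocol's).
#' @param recordings optional named list of pre-built `emg_recording`s
#'   keyed by subject id, bypassing generation.
#' @param seed master analysis seed.
#' @return object of class `cohort_report`: `results` (data.frame with one
#'   row per subject x loading), `summary` (per-loading mean, SE, n of the
#'   improvement over non-excluded subjects), `details` (list of
#'   `subject_result`).
#' @export
run_cohort <- function(profiles = NULL, protocol = protocol_spec(),
                       cfg = experiment_config(), loadings = NULL,
                       recordings = NULL, seed = 1L) {
  if (is.null(profiles) && is.null(recordings)) {
    stop("provide `profiles` or `recordings`")
  }
  loadings <- loadings %||% protocol$loadings
  ids <- if (!is.null(recordings)) names(recordings) else {
    vapply(profiles, `[[`, character(1), "subject_id")
  }
  details <- list()
  rows <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    rec <- if (!is.null(recordings)) recordings[[id]] else {
      prot <- protocol
      prot$seed <- derive_seed(protocol$seed, id, "session")
      generate_session(profiles[[i]], prot)
    }
    for (ld in loadings) {
      res <- run_subject(rec, ld, cfg, seed = derive_seed(seed, id, ld),
                         subject_id = id)
      details[[paste(id, ld, sep = ".")]] <- res
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = id, loading = ld,
        severity = if (!is.null(profiles)) profiles[[i]]$severity else NA,
        accuracy_without = res$without$overall_accuracy,
        accuracy_with = res$with$overall_accuracy,
        improvement = res$improvement, excluded = res$excluded,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(results, results$loading), function(d) {
    inc <- d[!d$excluded, , drop = FALSE]
    data.frame(loading = d$loading[1], n = nrow(inc),
               n_excluded = sum(d$excluded),
               mean_improvement = mean(inc$improvement),
               se_improvement = stats::sd(inc$improvement) /
                 sqrt(max(1, nrow(inc))),
               mean_without = mean(d$accuracy_without),
               mean_with = mean(d$accuracy_with))
  }))
  rownames(summ) <- NULL
  structure(list(results = results, summary = summ, details = details),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  print(x$results, row.names = FALSE)
  cat("\nImprovement over non-excluded subjects (percentage points):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
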