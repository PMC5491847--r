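TASKS <- c("relax", "open", "grasp")
LOADINGS <- c("table", "sabd25", "sabd50")
DEFAULT_CHANNELS <- c("mDEL", "FCR", "FDS", "ECR", "EDC")

#' Annotated multichannel EMG recording
#'
#' Container for a block of surface EMG: a channels x time matrix of signed
#' amplitudes (arbitrary units), the sampling rate, ordered channel labels,
#' and a table of trial annotations marking the task-phase intervals.
#'
#' Annotations use 0-based, half-open sample intervals `[start_sample,
#' end_sample)`, so `end_sample - start_sample` is the trial length in
#' samples.  Tasks come from the closed vocabulary `relax`, `open`, `grasp`;
#' loading levels from `table` (arm supported), `sabd25`, `sabd50`
#' (shoulder-abduction load at 25% / 50% of maximum torque).
#'
#' @param samples numeric matrix, channels x time.
#' @param fs sampling rate in Hz.
#' @param channels character vector of unique channel labels, one per row of
#'   `samples`.  Conventionally `mDEL`, `FCR`, `FDS`, `ECR`, `EDC`.
#' @param annotations data.frame with columns `start_sample`, `end_sample`,
#'   `task`, `loading`, `repetition`, or `NULL` for none.
#' @return an object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs, channels = rownames(samples),
                          annotations = NULL) {
  samples <- as.matrix(samples)
  if (is.null(channels)) {
    stop("channel labels are required (rownames of `samples` or `channels`)")
  }
  rownames(samples) <- channels
  if (is.null(annotations)) {
    annotations <- empty_annotations()
  }
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  rec <- structure(
    list(samples = samples, fs = fs, channels = as.character(channels),
         annotations = annotations),
    class = "emg_recording")
  validate_recording(rec)
}

empty_annotations <- function() {
  data.frame(start_sample = integer(0), end_sample = integer(0),
             task = character(0), loading = character(0),
             repetition = integer(0), stringsAsFactors = FALSE)
}

#' Validate an `emg_recording`
#'
#' Checks every structural invariant: positive sampling rate, unique channel
#' labels matching the sample matrix, annotation intervals inside
#' `[0, n_samples)`, half-open and non-overlapping, and tasks/loadings drawn
#' from their closed vocabularies.
#'
#' @param rec an `emg_recording`.
#' @return `rec`, invisibly usable, after passing all checks.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "emg_recording"))
  if (!is.numeric(rec$fs) || length(rec$fs) != 1L || rec$fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  if (anyDuplicated(rec$channels)) {
    stop("channel labels must be unique")
  }
  if (nrow(rec$samples) != length(rec$channels)) {
    stop("`samples` must have one row per channel")
  }
  if (!is.numeric(rec$samples)) stop("`samples` must be numeric")
  ann <- rec$annotations
  need <- c("start_sample", "end_sample", "task", "loading", "repetition")
  if (!all(need %in% names(ann))) {
    stop("annotations must have columns ", paste(need, collapse = ", "))
  }
  n <- ncol(rec$samples)
  if (nrow(ann)) {
    bad <- which(ann$start_sample < 0 | ann$end_sample > n |
                   ann$start_sample >= ann$end_sample)
    if (length(bad)) {
      stop(sprintf(
        "annotation %d ([%d,%d) %s/%s rep %d) outside [0,%d) or empty",
        bad[1], ann$start_sample[bad[1]], ann$end_sample[bad[1]],
        ann$task[bad[1]], ann$loading[bad[1]], ann$repetition[bad[1]], n))
    }
    if (!all(ann$task %in% TASKS)) {
      stop("annotation tasks must be one of: ", paste(TASKS, collapse = ", "))
    }
    if (!all(ann$loading %in% LOADINGS)) {
      stop("annotation loadings must be one of: ",
           paste(LOADINGS, collapse = ", "))
    }
    if (any(ann$repetition < 1)) stop("repetition indices must be >= 1")
    o <- order(ann$start_sample)
    if (any(ann$end_sample[o][-length(o)] > ann$start_sample[o][-1])) {
      stop("annotations must be non-overlapping")
    }
  }
  invisible(rec)
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  cat(sprintf("  annotations: %d trial(s)\n", nrow(x$annotations)))
  invisible(x)
}

#' Concatenated task-phase EMG for one (task, loading) cell
#'
#' @param samples channels x time matrix.
#' @param fs sampling rate in Hz.
#' @param channels channel labels.
#' @param task,loading the cell this signal belongs to.
#' @param source_trials integer repetition ids, in concatenation order.
#' @param boundaries cumulative sample offsets (0-based) at which each
#'   contributing trial starts, plus the total length as last element.
#' @return an object of class `task_signal`.
#' @export
task_signal <- function(samples, fs, channels = rownames(samples),
                        task = NA_character_, loading = NA_character_,
                        source_trials = integer(0), boundaries = NULL) {
  samples <- as.matrix(samples)
  rownames(samples) <- channels
  if (is.null(boundaries)) boundaries <- c(0L, ncol(samples))
  structure(
    list(samples = samples, fs = fs, channels = as.character(channels),
         task = task, loading = loading,
         source_trials = as.integer(source_trials),
         boundaries = as.integer(boundaries)),
    class = "task_signal")
}

#' @export
print.task_signal <- function(x, ...) {
  cat(sprintf("<task_signal> %s/%s: %d channel(s) x %d samples (%d trial(s))\n",
              x$task, x$loading, nrow(x$samples), ncol(x$samples),
              length(x$source_trials)))
  invisible(x)
}

#' Read an EMG recording from a CSV sample file plus metadata sidecar
#'
#' The sample file is delimited text with one header row of channel labels
#' and one column per channel.  The sidecar is a YAML document with fields
#' `fs`, `channels`, and a list `annotations` of records with `start_sample`,
#' `end_sample`, `task`, `loading`, `repetition`.
#'
#' @param data_path path to the CSV sample file.
#' @param meta_path path to the YAML metadata sidecar; defaults to
#'   `data_path` with extension replaced by `.yaml`.
#' @return an `emg_recording`.
#' @export
read_recording <- function(data_path, meta_path = default_meta_path(data_path)) {
  if (!file.exists(data_path)) stop("sample file not found: ", data_path)
  if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path)
  meta <- yaml::read_yaml(meta_path)
  if (is.null(meta$fs)) stop(meta_path, ": metadata must declare `fs`")
  dt <- data.table::fread(data_path, header = TRUE, sep = ",")
  channels <- as.character(meta$channels %||% names(dt))
  missing <- setdiff(channels, names(dt))
  if (length(missing)) {
    stop(sprintf("%s: missing channel column(s): %s", data_path,
                 paste(missing, collapse = ", ")))
  }
  for (ch in channels) {
    col <- dt[[ch]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      stop(sprintf("%s: non-numeric value in column '%s' at data row %d",
                   data_path, ch, if (is.na(bad)) NA_integer_ else bad))
    }
  }
  samples <- t(as.matrix(dt[, channels, with = FALSE]))
  ann <- annotations_from_meta(meta$annotations, meta_path)
  emg_recording(samples, fs = meta$fs, channels = channels, annotations = ann)
}

annotations_from_meta <- function(records, meta_path) {
  if (is.null(records) || !length(records)) return(empty_annotations())
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    need <- c("start_sample", "end_sample", "task", "loading", "repetition")
    if (!all(need %in% names(r))) {
      stop(sprintf("%s: annotation %d lacks field(s): %s", meta_path, i,
                   paste(setdiff(need, names(r)), collapse = ", ")))
    }
    data.frame(start_sample = as.integer(r$start_sample),
               end_sample = as.integer(r$end_sample),
               task = as.character(r$task), loading = as.character(r$loading),
               repetition = as.integer(r$repetition),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

default_meta_path <- function(data_path) {
  paste0(sub("\\.[^./]*$", "", data_path), ".yaml")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an EMG recording to CSV + YAML sidecar
#'
#' Inverse of [read_recording()]: samples go to a comma-separated file with
#' one header row (channel order preserved), metadata and annotations to a
#' YAML sidecar.  Samples are serialized with 15 significant digits, so a
#' round trip preserves them to better than 1e-9 relative.
#'
#' @param rec an `emg_recording`.
#' @param data_path output CSV path.
#' @param meta_path output YAML path.
#' @return invisibly, the two paths.
#' @export
write_recording <- function(rec, data_path,
                            meta_path = default_meta_path(data_path)) {
  validate_recording(rec)
  dt <- data.table::as.data.table(t(rec$samples))
  data.table::setnames(dt, rec$channels)
  data.table::fwrite(dt, data_path, sep = ",", scipen = 0)
  ann <- rec$annotations
  meta <- list(
    fs = rec$fs,
    channels = as.list(rec$channels),
    annotations = lapply(seq_len(nrow(ann)), function(i) {
      list(start_sample = ann$start_sample[i], end_sample = ann$end_sample[i],
           task = ann$task[i], loading = ann$loading[i],
           repetition = ann$repetition[i])
    }))
  yaml::write_yaml(meta, meta_path, precision = 15L)
  invisible(c(data = data_path, meta = meta_path))
}
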