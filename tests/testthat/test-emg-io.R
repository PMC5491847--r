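make_test_recording <- function(n = 5000, fs = 1000, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(5 * n), 5, n)
  ann <- data.frame(start_sample = c(0L, 2000L), end_sample = c(1500L, 4500L),
                    task = c("grasp", "relax"),
                    loading = c("sabd50", "sabd50"),
                    repetition = c(1L, 2L))
  emg_recording(X, fs = fs, channels = c("mDEL", "FCR", "FDS", "ECR", "EDC"),
                annotations = ann)
}

test_that("recording round-trips losslessly through CSV + YAML", {
  rec <- make_test_recording()
  d <- withr::local_tempdir()
  data_path <- file.path(d, "rec.csv")
  write_recording(rec, data_path)
  back <- read_recording(data_path)
  expect_identical(back$channels, rec$channels)
  expect_identical(back$fs, rec$fs)
  expect_equal(back$annotations, rec$annotations)
  expect_lt(max(abs(back$samples - rec$samples)) /
              max(abs(rec$samples)), 1e-9)
  # empty annotation list is allowed
  rec2 <- emg_recording(rec$samples, rec$fs, rec$channels)
  write_recording(rec2, file.path(d, "rec2.csv"))
  expect_equal(nrow(read_recording(file.path(d, "rec2.csv"))$annotations), 0L)
})

test_that("invariant violations are rejected with informative errors", {
  X <- matrix(rnorm(10), 2, 5)
  expect_error(
    emg_recording(X, fs = 1000, channels = c("a", "b"),
                  annotations = data.frame(start_sample = 0, end_sample = 6,
                                           task = "open", loading = "table",
                                           repetition = 1)),
    "outside \\[0,5\\)")
  expect_error(emg_recording(X, fs = -1, channels = c("a", "b")), "fs")
  expect_error(emg_recording(X, fs = 1000, channels = c("a", "a")), "unique")
  ov <- data.frame(start_sample = c(0, 2), end_sample = c(3, 5),
                   task = "open", loading = "table", repetition = 1:2)
  expect_error(emg_recording(X, fs = 1000, channels = c("a", "b"),
                             annotations = ov), "non-overlapping")
})

test_that("reader reports missing columns and bad cells by name", {
  set.seed(4)
  rec <- emg_recording(matrix(rnorm(5 * 50), 5, 50), fs = 1000,
                       channels = c("mDEL", "FCR", "FDS", "ECR", "EDC"))
  d <- withr::local_tempdir()
  data_path <- file.path(d, "rec.csv")
  write_recording(rec, data_path)
  # drop a channel column
  tab <- utils::read.csv(data_path, check.names = FALSE)
  utils::write.csv(tab[, -2], data_path, row.names = FALSE)
  expect_error(read_recording(data_path), "FCR")
  # corrupt a cell
  tab$FCR <- as.character(tab$FCR)
  tab$FCR[7] <- "oops"
  utils::write.csv(tab, data_path, row.names = FALSE)
  expect_error(read_recording(data_path), "non-numeric")
})

test_that("band-pass preprocessing has the 5-450 Hz response", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)[-1]
  tone <- function(f) sin(2 * pi * f * t)
  mid <- function(x) x[(length(x) %/% 4):(3 * length(x) %/% 4)]
  X <- rbind(tone(2), tone(100), tone(470))
  rec <- emg_recording(X, fs, c("a", "b", "c"))
  out <- bandpass_preprocess(rec)
  expect_lt(rms(mid(out$samples[1, ])), 0.1 * rms(mid(X[1, ])))
  expect_equal(rms(mid(out$samples[2, ])), rms(mid(X[2, ])), tolerance = 0.1)
  expect_lt(rms(mid(out$samples[3, ])), 0.5 * rms(mid(X[3, ])))
  # idempotent to ~1 dB in the passband
  twice <- bandpass_preprocess(out)
  r <- rms(mid(twice$samples[2, ])) / rms(mid(out$samples[2, ]))
  expect_gt(20 * log10(r), -1)
  expect_error(bandpass_preprocess(rec, 5, 500), "Nyquist")
})

test_that("segment_concatenate stitches matching trials in repetition order", {
  set.seed(2)
  fs <- 1000
  X <- matrix(rnorm(2 * 9000), 2, 9000)
  # out-of-order repetitions on purpose
  ann <- data.frame(start_sample = c(0L, 3000L, 6000L),
                    end_sample = c(2000L, 5000L, 8000L),
                    task = "grasp", loading = "sabd25",
                    repetition = c(2L, 1L, 3L))
  rec <- emg_recording(X, fs, c("a", "b"), ann)
  ts <- segment_concatenate(rec, "grasp", "sabd25")
  expect_equal(ncol(ts$samples), 6000)
  expect_identical(ts$source_trials, c(1L, 2L, 3L))
  manual <- cbind(X[, 3001:5000], X[, 1:2000], X[, 6001:8000])
  expect_identical(unname(ts$samples), manual)
  expect_identical(ts$boundaries, c(0L, 2000L, 4000L, 6000L))
  expect_error(segment_concatenate(rec, "open", "sabd25"),
               "open.*sabd25")
})

test_that("a 12-repetition cell concatenates to 60,000 samples", {
  p <- subject_profile(severity = 0)
  prot <- protocol_spec(loadings = "sabd50", repetitions = 12, seed = 5)
  rec <- generate_session(p, prot)
  ts <- segment_concatenate(rec, "open", "sabd50")
  expect_equal(ncol(ts$samples), 60000L)
  expect_equal(length(ts$source_trials), 12L)
})
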