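test_that("merge_bands unions intervals like a lattice oracle", {
  b1 <- merge_bands(list(grasp = frequency_band(8, 11),
                         open = frequency_band(10, 13),
                         relax = empty_bands()))
  expect_equal(nrow(b1), 1L)
  expect_equal(c(b1$lo_hz, b1$hi_hz), c(8, 13))
  expect_equal(nrow(merge_bands(list(empty_bands(), empty_bands()))), 0L)
  b2 <- merge_bands(list(frequency_band(12, 13), frequency_band(8, 9)))
  expect_equal(b2$lo_hz, c(8, 12))
  expect_equal(b2$hi_hz, c(9, 13))
  # randomized check against the brute-force lattice union
  set.seed(13)
  for (i in 1:20) {
    bl <- lapply(1:3, function(j) {
      k <- sample(0:3, 1)
      if (k == 0) return(empty_bands())
      lo <- round(runif(k, 1, 90), 1)
      frequency_band(lo, lo + round(runif(k, 0, 8), 1))
    })
    m <- merge_bands(bl)
    lat <- lattice_union(bl)
    expect_equal(nrow(m), nrow(lat))
    if (nrow(m)) {
      expect_true(all(abs(m$lo_hz - lat$lo_hz) <= 0.051))
      expect_true(all(abs(m$hi_hz - lat$hi_hz) <= 0.051))
    }
  }
})

test_that("exclusion rule fires on empty or peak-only band sets", {
  expect_false(exclusion_rule(empty_bands()))
  expect_false(exclusion_rule(frequency_band(10, 10)))
  expect_true(exclusion_rule(frequency_band(8, 12)))
  expect_false(exclusion_rule(frequency_band(c(9, 11), c(9, 11)), 0.1))
  expect_true(exclusion_rule(rbind(frequency_band(9, 9),
                                   frequency_band(11, 13)), 0.1))
})

test_that("band-stop design meets its response contract and stays stable", {
  fs <- 1000
  casc <- design_bandstop(frequency_band(8, 13), fs)
  f0 <- sqrt(8 * 13)
  h <- cohemg:::cascade_response(casc, c(f0, 35), fs)
  expect_lt(20 * log10(Mod(h[1])), -20)
  expect_lt(abs(20 * log10(Mod(h[2]))), 1)
  # random narrow-to-wide bands in (3, 100) Hz all stable
  set.seed(14)
  for (i in 1:25) {
    lo <- runif(1, 3, 95)
    hi <- lo + runif(1, 0.05, 30)
    casc <- design_bandstop(frequency_band(lo, min(hi, 99.9)), fs)
    for (st in casc) {
      for (s2 in st$sos) {
        expect_true(all(Mod(polyroot(rev(s2$a))) < 1))
      }
    }
  }
  expect_error(design_bandstop(frequency_band(0.5, 1.2), fs), "touches")
  expect_error(design_bandstop(frequency_band(499, 499.9), fs), "touches")
})

test_that("narrow bands are padded to the minimum stop width", {
  casc <- design_bandstop(frequency_band(10, 10.2), 1000)
  expect_equal(casc[[1]]$hi_hz - casc[[1]]$lo_hz, 2)
  expect_equal((casc[[1]]$hi_hz + casc[[1]]$lo_hz) / 2, 10.1)
})

test_that("filter banks attenuate stop-band tones, pass others, and leave
           unfiltered channels bit-identical", {
  fs <- 1000
  t <- (0:29999) / fs
  X <- rbind(sin(2 * pi * 10 * t), sin(2 * pi * 30 * t),
             sin(2 * pi * 10 * t))
  sig <- task_signal(X, fs, c("FDS", "FCR", "EDC"), task = "grasp",
                     loading = "sabd50", source_trials = 1L)
  bank <- filter_bank(list(FDS = frequency_band(8, 13),
                           FCR = frequency_band(8, 13),
                           EDC = empty_bands()),
                      fs = fs, subject_id = "S1", loading = "sabd50")
  out <- apply_filterbank(sig, bank)
  mid <- 5000:25000
  expect_lt(rms(out$samples["FDS", mid]) / rms(X[1, mid]), 0.05)
  expect_equal(rms(out$samples["FCR", mid]) / rms(X[2, mid]), 1,
               tolerance = 0.1)
  expect_identical(out$samples["EDC", ], sig$samples["EDC", ])
  expect_equal(ncol(out$samples), ncol(sig$samples))
  # ineligible bank is a pass-through
  off <- filter_bank(list(FDS = frequency_band(8, 13)), fs,
                     eligible = FALSE)
  expect_identical(apply_filterbank(sig, off)$samples, sig$samples)
  bad <- filter_bank(list(mDEL = frequency_band(8, 13)), fs)
  expect_error(apply_filterbank(sig, bad), "missing")
})

test_that("broadband energy outside the stop bands survives filtering", {
  fs <- 1000
  set.seed(15)
  x <- rnorm(60000)
  casc <- design_bandstop(frequency_band(8, 13), fs)
  y <- cohemg:::apply_cascade(x, casc)
  # Parseval-style check on the spectrum outside the band (+/- 2 Hz guard)
  X <- Mod(fft(x))^2
  Y <- Mod(fft(y))^2
  f <- (seq_along(X) - 1) / length(X) * fs
  f <- pmin(f, fs - f)
  outside <- f < 6 | (f > 15 & f <= fs / 2)
  expect_equal(sum(Y[outside]) / sum(X[outside]), 1, tolerance = 0.1)
})

test_that("build_subject_filters finds flexor alpha bands for synthetic
           stroke subjects and leaves controls ineligible", {
  prot <- protocol_spec(loadings = "sabd50", repetitions = 6, seed = 21)
  stroke <- subject_profile(severity = 1, subject_id = "P1")
  rec <- generate_session(stroke, prot)
  rec <- bandpass_preprocess(rec)
  banks <- build_subject_filters(rec, coherence_config(n_surrogates = 100),
                                 seed = 3, subject_id = "P1")
  bank <- banks[["sabd50"]]
  expect_true(bank$eligible)
  for (ch in c("FDS", "FCR")) {
    b <- bank$stop_bands[[ch]]
    expect_gt(nrow(b), 0)
    covers_alpha <- any(b$lo_hz <= 9 & b$hi_hz >= 12)
    expect_true(covers_alpha)
  }
  # separate loadings yield separate banks
  prot2 <- protocol_spec(loadings = c("sabd25", "sabd50"), repetitions = 4,
                         seed = 22)
  rec2 <- generate_session(stroke, prot2)
  banks2 <- build_subject_filters(rec2,
                                  coherence_config(n_surrogates = 100),
                                  seed = 4, subject_id = "P1")
  expect_setequal(names(banks2), c("sabd25", "sabd50"))
  expect_error(
    build_subject_filters(
      generate_session(stroke, protocol_spec(tasks = c("open", "grasp"),
                                             loadings = "sabd50",
                                             repetitions = 2, seed = 1)),
      coherence_config(n_surrogates = 100)),
    "lacks task")
})
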