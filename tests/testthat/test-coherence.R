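test_that("Morlet CWT localizes a tone, is linear, and rejects short input", {
  fs <- 1000
  cfg <- coherence_config()
  t <- (0:7999) / fs
  x <- sin(2 * pi * 10 * t)
  W <- morlet_cwt(x, fs, cfg)
  freqs <- attr(W, "freqs")
  coi <- attr(W, "coi")
  mid <- which(attr(W, "times") > 2 & attr(W, "times") < 6)
  peak_f <- freqs[apply(Mod(W[, mid]), 2, which.max)]
  expect_equal(median(peak_f), freqs[which.min(abs(freqs - 10))])
  # linearity
  set.seed(1)
  y <- rnorm(8000)
  Wy <- morlet_cwt(y, fs, cfg)
  Wsum <- morlet_cwt(x + y, fs, cfg)
  expect_lt(max(Mod(Wsum - (W + Wy))) / max(Mod(Wsum)), 1e-9)
  Wsc <- morlet_cwt(3.7 * x, fs, cfg)
  expect_lt(max(Mod(Wsc - 3.7 * W)) / max(Mod(Wsc)), 1e-9)
  expect_error(morlet_cwt(rnorm(500), fs, cfg), "short")
})

test_that("wavelet coherence is bounded, symmetric, one on self", {
  fs <- 1000
  cfg <- coherence_config()
  set.seed(2)
  for (i in 1:5) {
    x <- rnorm(6000)
    y <- stats::filter(rnorm(6000), 0.6, method = "recursive")
    m <- wavelet_coherence(x, as.numeric(y), fs, cfg)
    expect_true(all(m$values >= 0 & m$values <= 1 + 1e-9))
    m2 <- wavelet_coherence(as.numeric(y), x, fs, cfg)
    expect_lt(max(abs(m$values - m2$values)), 1e-9)
  }
  x <- rnorm(6000)
  ms <- wavelet_coherence(x, x, fs, cfg)
  expect_gte(min(ms$values[in_coi(ms)]), 0.99)
  expect_error(wavelet_coherence(rnorm(100), rnorm(101), fs, cfg), "equal")
  expect_error(wavelet_coherence(numeric(6000), rnorm(6000), fs, cfg),
               "zero")
})

test_that("independent noise stays low, a shared tone is picked up", {
  fs <- 1000
  cfg <- coherence_config()
  set.seed(3)
  means <- replicate(5, {
    m <- wavelet_coherence(rnorm(10000), rnorm(10000), fs, cfg)
    mean(m$values[in_coi(m)])
  })
  expect_lt(mean(means), 0.5)
  t <- (0:9999) / fs
  s <- sin(2 * pi * 10 * t)
  m <- wavelet_coherence(s + rnorm(10000), s + rnorm(10000), fs, cfg)
  band <- which(m$freqs >= 9 & m$freqs <= 11)
  expect_gt(median(m$values[band, ][in_coi(m)[band, ]]), 0.7)
})

test_that("Monte-Carlo thresholds are valid, seeded, and respond to
           smoothing as more averaging", {
  fs <- 1000
  cfg <- fast_cfg()
  set.seed(4)
  x <- as.numeric(stats::filter(rnorm(8000), 0.5, method = "recursive"))
  y <- rnorm(8000)
  thr1 <- monte_carlo_threshold(x, y, fs, cfg, seed = 9)
  thr2 <- monte_carlo_threshold(x, y, fs, cfg, seed = 9)
  expect_identical(thr1, thr2)
  expect_true(all(thr1 > 0 & thr1 < 1))
  expect_error(
    monte_carlo_threshold(x, y, fs, coherence_config(n_surrogates = 50)),
    ">= 100")
  # doubling the time-smoothing width lowers the null quantiles
  wide <- fast_cfg(time_smooth = 2)
  for (sd in 1:3) {
    a <- monte_carlo_threshold(x, y, fs, fast_cfg(), seed = sd)
    b <- monte_carlo_threshold(x, y, fs, wide, seed = sd)
    expect_true(all(b <= a + 0.02))
    expect_lt(mean(b), mean(a))
  }
})

test_that("global coherence aggregates power and applies the occupancy
           rule", {
  fs <- 1000
  cfg <- coherence_config()
  set.seed(5)
  m <- wavelet_coherence(rnorm(8000), rnorm(8000), fs, cfg)
  expect_error(global_coherence(m), "threshold")
  # all-ones map -> power 1 everywhere
  m1 <- m
  m1$values[] <- 1
  m1 <- set_threshold(m1, rep(0.9, length(m$freqs)))
  g1 <- global_coherence(m1)
  expect_true(all(g1$power[!is.na(g1$power)] == 1))
  expect_true(all(g1$significance[!is.na(g1$power)]))
  # shared tone -> significant at the nearest grid frequency
  t <- (0:9999) / fs
  s <- sin(2 * pi * 10 * t)
  x <- s + rnorm(10000); y <- s + rnorm(10000)
  m2 <- wavelet_coherence(x, y, fs, cfg)
  m2 <- set_threshold(m2, monte_carlo_threshold(x, y, fs, fast_cfg(),
                                                seed = 6))
  g2 <- global_coherence(m2)
  expect_true(g2$significance[which.min(abs(g2$freqs - 10))])
})

test_that("independent-noise pairs rarely reach global significance", {
  fs <- 1000
  cfg <- fast_cfg()
  set.seed(6)
  frac_sig <- replicate(10, {
    x <- rnorm(10000); y <- rnorm(10000)
    m <- wavelet_coherence(x, y, fs, cfg)
    m <- set_threshold(m, monte_carlo_threshold(x, y, fs, cfg,
                                                seed = sample.int(1e6, 1)))
    mean(global_coherence(m)$significance)
  })
  expect_gte(mean(frac_sig <= 0.10), 0.9)
})

test_that("significant_bands extracts maximal runs and peak-only bands", {
  gc <- structure(
    list(freqs = c(8, 9, 10, 11, 12), power = rep(0.5, 5),
         significance = c(FALSE, TRUE, TRUE, TRUE, FALSE),
         occupancy_frac = rep(0.5, 5), occupancy = 0.25),
    class = "global_coherence")
  b <- significant_bands(gc)
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$lo_hz, b$hi_hz), c(9, 11))
  gc$significance <- rep(FALSE, 5)
  expect_equal(nrow(significant_bands(gc)), 0L)
  gc$significance <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  b2 <- significant_bands(gc)
  expect_equal(nrow(b2), 1L)
  expect_equal(b2$lo_hz, b2$hi_hz)
  gc$significance <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  b3 <- significant_bands(gc)
  expect_equal(b3$lo_hz, c(8, 11))
  expect_equal(b3$hi_hz, c(9, 11))
})
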