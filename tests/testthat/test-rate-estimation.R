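test_that("autocorrelation is normalized and equals the direct sum", {
  set.seed(41)
  x <- rnorm(256)
  R <- autocorrelation(x)
  expect_equal(R[1], 1)

  # brute-force biased estimator
  xc <- x - mean(x)
  direct <- vapply(0:(length(x) - 1), function(m) {
    sum(xc[1:(length(x) - m)] * xc[(1 + m):length(x)])
  }, numeric(1))
  expect_lt(max(abs(R - direct / direct[1])), 1e-10)

  # periodic signal: local maximum at the period with R > 0.8
  P <- 25
  xp <- sin(2 * pi * (0:999) / P)
  Rp <- autocorrelation(xp)
  expect_gt(Rp[P + 1], 0.8)
  expect_gt(Rp[P + 1], max(Rp[c(P, P + 2)]) - 1e-12)

  expect_error(autocorrelation(rep(2, 50)), "variance")
})

test_that("autocorrelation rate picks the in-band period", {
  fs <- 20
  x <- sin(2 * pi * 1.54 * (0:1199) / fs)
  est <- rate_from_autocorr(autocorrelation(x), fs, c(0.8, 2))
  expect_equal(est$frequency, fs / 13) # lag quantum: 13 -> 1.538 Hz
  expect_equal(est$rate, 60 * est$frequency)

  # white noise: no strong periodicity
  set.seed(42)
  w <- rnorm(1200)
  out <- tryCatch(rate_from_autocorr(autocorrelation(w), fs, c(0.8, 2)),
                  error = function(e) e)
  expect_true(inherits(out, "error") || !is.na(out$flag))

  # band excluding every multiple of the true period: error, not a
  # silent out-of-band estimate
  expect_error(rate_from_autocorr(autocorrelation(x), fs, c(1.7, 1.99)),
               "no periodicity|no admissible")
})

test_that("peak-count rate follows the counting formula", {
  fs <- 20
  x <- sin(2 * pi * 1 * (0:1199) / fs) # 60 peaks in 60 s
  est <- rate_from_peaks(x, fs)
  expect_equal(est$rate, 60)

  flat <- rate_from_peaks(rep(0, 100), fs)
  expect_equal(flat$rate, 0)
  expect_equal(flat$flag, "no peaks")

  # doubling the window leaves the rate invariant
  x2 <- sin(2 * pi * 1 * (0:2399) / fs)
  expect_equal(rate_from_peaks(x2, fs)$rate, 60)
})

test_that("spectral peak is exact on bin frequencies and picks the max", {
  fs <- 20
  n <- 1024
  f_true <- 40 * fs / 2048 # exact bin of the default-padded FFT
  x <- sin(2 * pi * f_true * (0:(n - 1)) / fs)
  expect_equal(spectral_peak(x, fs, c(0.1, 2), n_fft = 2048)$frequency,
               f_true)

  two <- sin(2 * pi * 1.0 * (0:1199) / fs) +
    0.4 * sin(2 * pi * 1.5 * (0:1199) / fs)
  expect_equal(spectral_peak(two, fs, c(0.8, 2))$frequency, 1.0,
               tolerance = 0.01)
  expect_error(spectral_peak(two, fs, c(10.5, 11)), "empty")
})

test_that("rmse matches hand arithmetic and is a metric-like score", {
  expect_equal(rmse(c(70, 72, 74), c(70, 72, 74)), 0)
  expect_equal(rmse(c(70, 72, 74), c(72, 74, 76)), 2)
  expect_equal(rmse(c(70, 72, 74), c(71, 70, 75)), sqrt(2))
  perm <- c(3, 1, 2)
  a <- c(70, 72, 74)
  b <- c(71, 70, 75)
  expect_equal(rmse(a[perm], b[perm]), rmse(a, b))
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("pure sinusoid estimators agree within quantization", {
  fs <- 20
  x <- sin(2 * pi * 1.3 * (0:1199) / fs)
  f_ac <- rate_from_autocorr(autocorrelation(x), fs, c(0.8, 2))$frequency
  f_sp <- spectral_peak(x, fs, c(0.8, 2))$frequency
  f_pk <- rate_from_peaks(x, fs)$frequency
  # lag quantum at 1.3 Hz is the coarsest of the three grids
  quant <- fs / 15 - fs / 16
  expect_lt(abs(f_ac - 1.3), quant + 1e-9)
  expect_lt(abs(f_sp - 1.3), 0.01)
  expect_lt(abs(f_pk - 1.3), 0.02)
})

test_that("stream processing windows are stable and well-counted", {
  # stationary signal: every window agrees within one quantum
  sim <- simulate_vital_phase(duration = 40, rng_seed = 31)
  cfg <- eemd_config(n_ensemble = 10, rng_seed = 55)
  df <- stream_process(sim$phase, window = 20, step = 10, cfg,
                       method = "spectral")
  expect_equal(nrow(df), 3) # floor((40 - 20)/10) + 1
  expect_lt(diff(range(df$heart_hz)), 0.06)
  expect_lt(diff(range(df$respiration_hz)), 0.06)
  expect_equal(df$time, c(20, 30, 40), tolerance = 0.1)

  # step = duration gives exactly one window
  one <- stream_process(sim$phase, window = 40, step = 40, cfg,
                        method = "spectral")
  expect_equal(nrow(one), 1)

  expect_error(stream_process(sim$phase, window = 100, step = 1, cfg),
               "longer than")
})
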