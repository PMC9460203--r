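test_that("EMD separates well-spaced tones and reconstructs exactly", {
  # monotone input: no oscillation to extract
  ramp <- seq(0, 1, length.out = 100)
  fit0 <- emd(ramp, eemd_config(), fs = 10)
  expect_length(fit0$imfs, 0)
  expect_equal(fit0$residual, ramp)

  # two well-separated tones land in IMF1 (fast) and IMF2 (slow)
  t <- test_time(fs = 50, duration = 60)
  fast <- sin(2 * pi * 3 * t)
  slow <- sin(2 * pi * 0.3 * t)
  fit <- emd(fast + slow, eemd_config(), fs = 50)
  expect_gte(length(fit$imfs), 2)
  expect_equal(peak_freq(fit$imfs[[1]], 50, c(0.1, 10)), 3,
               tolerance = 0.05)
  expect_equal(peak_freq(fit$imfs[[2]], 50, c(0.1, 10)), 0.3,
               tolerance = 0.05)
  expect_gt(stats::cor(fit$imfs[[1]], fast), 0.95)
  expect_gt(stats::cor(fit$imfs[[2]], slow), 0.95)

  # completeness on a noisy input
  x <- standard_phase(21)$phase$samples
  fit2 <- emd(x, eemd_config(), fs = 20)
  recon <- Reduce(`+`, fit2$imfs) + fit2$residual
  expect_lt(max(abs(recon - x)) / stats::sd(x), 1e-8)

  # IMF extrema/zero-crossing balance on converged (clean) modes; on
  # noisy input the Cauchy-stopped sift approximates it (see vignette)
  for (imf in fit$imfs) {
    ext <- find_extrema(imf)
    n_ext <- length(ext$maxima) + length(ext$minima)
    n_zc <- sum(abs(diff(sign(imf[imf != 0]))) > 0)
    expect_lte(abs(n_ext - n_zc), 1)
  }
})

test_that("ensemble decomposition degenerates and is reproducible", {
  x <- standard_phase(22)$phase$samples

  # Nstd = 0 collapses to plain EMD exactly
  e0 <- eemd(x, eemd_config(Nstd = 0, n_ensemble = 1,
                            noise_kind = "gaussian"), fs = 20)
  ref <- emd(x, eemd_config(), fs = 20)
  expect_identical(e0$imfs, ref$imfs)
  expect_identical(e0$residual, ref$residual)

  # fixed seed: bit-identical ensembles
  cfg <- eemd_config(n_ensemble = 10, noise_kind = "gaussian",
                     rng_seed = 5)
  expect_identical(eemd(x, cfg, fs = 20)$imfs,
                   eemd(x, cfg, fs = 20)$imfs)

  # ensemble completeness: residual defined by subtraction
  e1 <- eemd(x, cfg, fs = 20)
  recon <- Reduce(`+`, e1$imfs) + e1$residual
  expect_equal(recon, x)
})

test_that("termination criteria follow extrema rate and amplitude", {
  t <- test_time(fs = 20, duration = 60)
  bands <- vital_bands()

  # 0.3 Hz sinusoid over 60 s: 18 maxima + 18 minima -> sigma = 0.3 Hz
  chk <- termination_check(sin(2 * pi * 0.3 * t), 60, bands)
  expect_equal(chk$sigma, 0.3)

  # constant series: no extrema
  chk0 <- termination_check(rep(1, 100), 60, bands)
  expect_equal(chk0$sigma, 0)
  expect_false(chk0$stop)

  # amplitude window is a strict conjunction with the frequency window
  small <- sin(2 * pi * 0.3 * t) # gamma = 2 rad, below the lower bound
  chk1 <- termination_check(small, 60, bands)
  expect_false(chk1$stop)
  ok <- 10 * sin(2 * pi * 0.3 * t) # gamma = 20 rad, inside
  expect_true(termination_check(ok, 60, bands)$stop)
  # in-band frequency but amplitude above the window
  big <- 30 * sin(2 * pi * 0.3 * t)
  expect_false(termination_check(big, 60, bands)$stop)

  # the 2pi/lambda variant halves the admissible gamma window
  b2 <- vital_bands(phase_factor = "2pi")
  expect_true(termination_check(5 * sin(2 * pi * 0.3 * t), 60,
                                b2)$stop)
})

test_that("adaptive decomposition stops early without altering history", {
  x <- standard_phase(23)$phase$samples
  cfg_small <- eemd_config(n_ensemble = 20, rng_seed = 77)
  fit <- improved_eemd(x, cfg_small, fs = 20)
  cfg_full <- cfg_small
  cfg_full$adaptive_termination <- FALSE
  full <- improved_eemd(x, cfg_full, fs = 20)

  # strictly fewer stages, and the emitted prefix is unchanged
  expect_lt(fit$stages, full$stages)
  for (q in seq_along(fit$imfs)) {
    expect_identical(fit$imfs[[q]], full$imfs[[q]])
  }

  # termination labels the respiration mode; heartbeat precedes it
  expect_equal(fit$labels$respiration, length(fit$imfs))
  expect_lt(fit$labels$heartbeat, fit$labels$respiration)

  # diagnostics recorded per emitted IMF
  expect_equal(nrow(fit$diagnostics), length(fit$imfs))
  expect_true(all(fit$diagnostics$sigma >= 0))

  # pure in-band tone with admissible amplitude stops within 3 stages
  t <- test_time(fs = 20, duration = 60)
  tone <- 10 * sin(2 * pi * 0.3 * t)
  ftone <- improved_eemd(tone, eemd_config(n_ensemble = 10,
                                           rng_seed = 3), fs = 20)
  expect_true(ftone$terminated_early)
  expect_lte(length(ftone$imfs), 3)

  expect_error(
    improved_eemd(x, eemd_config(noise_kind = "gaussian"), fs = 20),
    "alpha_stable")
})

test_that("alpha = 2 ensemble noise reproduces Gaussian EEMD modes", {
  x <- standard_phase(3)$phase$samples
  imp <- improved_eemd(x, eemd_config(n_ensemble = 200, alpha = 2,
                                      rng_seed = 7,
                                      adaptive_termination = FALSE),
                       fs = 20)
  gau <- label_imfs(eemd(x, eemd_config(n_ensemble = 200,
                                        noise_kind = "gaussian",
                                        rng_seed = 8), fs = 20))
  expect_equal(imp$labels$heartbeat, gau$labels$heartbeat)
  expect_equal(imp$labels$respiration, gau$labels$respiration)
  q <- imp$labels$heartbeat
  rms_diff <- sqrt(mean((imp$imfs[[q]] - gau$imfs[[q]])^2))
  expect_lt(rms_diff / sqrt(mean(gau$imfs[[q]]^2)), 0.10)
})
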