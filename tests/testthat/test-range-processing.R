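test_that("clutter filter removes static returns and keeps periodic ones", {
  scene <- clutter_scene()
  filtered <- static_clutter_filter(scene$cube)

  # per-column slow-time mean is zero after filtering
  expect_lt(max(Mod(colMeans(filtered$data))), 1e-10)

  # static-bin slow-time power drops by > 40 dB, vital bin survives
  prof_raw <- range_fft(scene$cube)
  prof_flt <- range_fft(filtered)
  static_bin <- round(scene$static_range / prof_raw$bin_spacing) + 1L
  vital_bin <- round(scene$vital_range / prof_raw$bin_spacing) + 1L
  p_raw <- mean(Mod(prof_raw$profiles[, static_bin])^2)
  p_flt <- mean(Mod(prof_flt$profiles[, static_bin])^2)
  expect_gt(10 * log10(p_raw / p_flt), 40)

  expect_equal(select_target_bin(prof_flt), vital_bin)

  # the vital bin's periodic component is preserved: compare slow-time
  # magnitude-free phase trajectory against a clutter-free reference
  ref_cube <- simulate_if_cube(scene$config, list(
    scene_target(0.65, "vital", displacement = scene$displacement)),
    n_frames = nrow(scene$cube$data))
  ph_flt <- dacm_phase(iq_at_bin(prof_flt, vital_bin))$samples
  ph_ref <- dacm_phase(iq_at_bin(range_fft(ref_cube), vital_bin))$samples
  expect_gt(stats::cor(ph_flt, ph_ref), 0.99)
})

test_that("clutter filter contract: errors, constancy, idempotence", {
  cfg <- radar_config(n_samples = 8L)
  one <- if_cube(matrix(1 + 2i, 1, 8), cfg)
  expect_error(static_clutter_filter(one), "two frames")

  const <- if_cube(matrix(rep(3 - 1i, 40), 5, 8), cfg)
  expect_equal(static_clutter_filter(const)$data,
               matrix(0 + 0i, 5, 8))

  # zero-mean sinusoidal column over whole periods passes unchanged
  L <- 40L
  col <- sin(2 * pi * 4 * (0:(L - 1)) / L)
  cube <- if_cube(matrix(rep(col, 8), L, 8), cfg)
  expect_lt(max(Mod(static_clutter_filter(cube)$data - cube$data)),
            1e-10)

  # idempotent and linear
  set.seed(2)
  z <- matrix(complex(real = rnorm(80), imaginary = rnorm(80)), 10, 8)
  cube2 <- if_cube(z, cfg)
  once <- static_clutter_filter(cube2)
  twice <- static_clutter_filter(once)
  expect_equal(twice$data, once$data)
  scaled <- static_clutter_filter(if_cube(3 * z, cfg))
  expect_equal(scaled$data, 3 * once$data)
})

test_that("range FFT puts pure tones in their bins and conserves power", {
  cfg <- radar_config(n_samples = 64L, adc_rate = 64 / 60e-6)
  k <- 12
  row <- exp(2i * pi * k * (0:63) / 64)
  cube <- if_cube(matrix(row, 1, 64, byrow = TRUE), cfg)
  prof <- range_fft(cube, n_fft = 64)
  expect_equal(which.max(Mod(prof$profiles[1, ])), k + 1L)

  # Parseval with window = none
  expect_equal(sum(Mod(prof$profiles)^2),
               64 * sum(Mod(cube$data)^2), tolerance = 1e-12)

  expect_error(range_fft(cube, n_fft = 32), "n_fft")
  expect_equal(ncol(range_fft(cube)$profiles), 64) # next pow2 default
})

test_that("target-bin selection is variance-based with low-index ties", {
  cfg <- radar_config(n_samples = 4L)
  # constructed profiles: bins 2 and 3 oscillate identically
  osc <- c(1, -1, 1, -1)
  profs <- structure(list(
    profiles = cbind(0, osc, osc, 0) + 0i,
    bin_spacing = 0.0375, config = cfg),
    class = "range_profile_set")
  expect_equal(select_target_bin(profs), 2L)

  zero <- structure(list(profiles = matrix(0 + 0i, 4, 3),
                         bin_spacing = 0.0375, config = cfg),
                    class = "range_profile_set")
  expect_error(select_target_bin(zero), "no target")
})

test_that("range resolution follows c/(2B)", {
  expect_equal(range_resolution(4e9), 299792458 / 8e9)
  expect_equal(round(range_resolution(4e9), 2), 0.04)
  expect_equal(range_resolution(299792458 / 2), 1)
  expect_equal(range_resolution(2 * 4e9), range_resolution(4e9) / 2)
  expect_error(range_resolution(0))
})
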