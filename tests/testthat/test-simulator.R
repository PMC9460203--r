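test_that("displacement synthesis matches the analytic tone sum", {
  # zero-amplitude case
  p0 <- vital_sign_params(A_re = 0, A_hr = 0)
  expect_equal(simulate_displacement(p0, fs = 20, duration = 2),
               rep(0, 40))

  # half-period cosine symmetry: x[0] = 1, x[t = 2 s] = -1
  p1 <- vital_sign_params(A_re = 1, f_re = 0.25, A_hr = 0)
  x <- simulate_displacement(p1, fs = 20, duration = 4)
  expect_length(x, 80)
  expect_equal(x[1], 1)
  expect_equal(x[41], -1)

  # the reference configuration has spectral peaks at every component
  p <- vital_sign_params(f_re = 0.32, f_hr = 1.54,
                         harmonics = default_harmonics())
  xs <- simulate_displacement(p, fs = 20, duration = 60)
  expected <- c(0.32, 0.64, 0.96, 1.28, 1.54, 1.92)
  for (f in expected) {
    got <- peak_freq(xs, 20, f + c(-0.05, 0.05), n_fft = 16384)
    expect_lt(abs(got - f), 20 / 16384 + 1e-9)
  }
})

test_that("displacement synthesis is additive and rejects aliasing", {
  p_re <- vital_sign_params(A_re = 2e-3, f_re = 0.3, A_hr = 0)
  p_hr <- vital_sign_params(A_re = 0, A_hr = 4e-4, f_hr = 1.5)
  p_both <- vital_sign_params(A_re = 2e-3, f_re = 0.3,
                              A_hr = 4e-4, f_hr = 1.5)
  expect_equal(
    simulate_displacement(p_both, 20, 10),
    simulate_displacement(p_re, 20, 10) +
      simulate_displacement(p_hr, 20, 10))

  expect_error(simulate_displacement(p_both, fs = 2.5, duration = 10),
               "alias")
  expect_error(vital_sign_params(A_re = NaN), "finite")
})

test_that("phase map is the affine two-way carrier scaling", {
  lam <- 3.9e-3
  ph <- displacement_to_phase(rep(0, 10), lam, R = lam / 4)
  expect_equal(ph$samples, rep(pi, 10))

  d <- rep(0, 10)
  d[4] <- lam / 8
  expect_equal(displacement_to_phase(d, lam, R = 0)$samples[4], pi / 2)

  # affine: scaling and offsetting displacement scales/offsets phase
  x <- sin(seq(0, 4, length.out = 50))
  a <- 2.5
  b <- 1e-3
  lhs <- displacement_to_phase(a * x + b, lam, R = 0.5)$samples
  rhs <- a * (4 * pi / lam) * x + (4 * pi / lam) * (b + 0.5)
  expect_equal(lhs, rhs)

  # peak-to-peak of the reference signal's phase
  p <- vital_sign_params(harmonics = default_harmonics())
  d2 <- simulate_displacement(p, 20, 60)
  ph2 <- displacement_to_phase(d2, lam)$samples
  expect_equal(diff(range(ph2)), 4 * pi / lam * diff(range(d2)))
})

test_that("seeded noise is reproducible and has the requested scale", {
  x <- sin(seq(0, 20, length.out = 1e5))
  expect_identical(add_noise(x, 0, "gaussian"), x)
  expect_error(add_noise(x, -1), "nonnegative")

  y1 <- add_noise(x, 0.3, "gaussian", rng_seed = 5)
  y2 <- add_noise(x, 0.3, "gaussian", rng_seed = 5)
  expect_identical(y1, y2)

  # absolute scale: sd of the added noise within 5% of s at n = 1e5
  s <- 0.7
  ya <- add_noise(x, s, "gaussian", rng_seed = 6, relative = FALSE)
  expect_lt(abs(stats::sd(ya - x) - s) / s, 0.05)

  # alpha-stable with alpha = 2 is Gaussian
  yb <- add_noise(x[1:10000], 1, "alpha_stable", alpha = 2,
                  rng_seed = 7, relative = FALSE)
  ks <- stats::ks.test(yb - x[1:10000], "pnorm", sd = 1)
  expect_gt(ks$p.value, 0.01)
  expect_error(add_noise(x, 1, "alpha_stable", alpha = 2.5), "alpha")
})

test_that("IF cubes follow the single-tone beat model", {
  cfg <- radar_config()
  # static-only scene: all rows identical, zero slow-time variance
  cube <- simulate_if_cube(cfg, list(scene_target(1.0)), n_frames = 8)
  expect_true(all(apply(cube$data, 2, function(col) {
    max(Mod(col - col[1]))
  }) < 1e-12))

  # range-FFT peak at the closed-form beat bin
  prof <- range_fft(cube)
  got_bin <- which.max(Mod(prof$profiles[1, ]))
  expect_equal(got_bin, round(1.0 / prof$bin_spacing) + 1L)

  # the 0.65 m reference target lands within one bin of its range
  cube2 <- simulate_if_cube(cfg, list(scene_target(0.65)), n_frames = 2)
  prof2 <- range_fft(cube2)
  b2 <- which.max(Mod(prof2$profiles[1, ]))
  expect_lt(abs((b2 - 1) * prof2$bin_spacing - 0.65), prof2$bin_spacing)

  expect_error(simulate_if_cube(cfg, list(), 4), "at least one")
  expect_error(
    simulate_if_cube(cfg, list(scene_target(1e5)), 2), "range")

  # seeded reproducibility
  c1 <- simulate_if_cube(cfg, list(scene_target(1)), 4,
                         noise_scale = 0.1, rng_seed = 9)
  c2 <- simulate_if_cube(cfg, list(scene_target(1)), 4,
                         noise_scale = 0.1, rng_seed = 9)
  expect_identical(c1$data, c2$data)
})

test_that("radar configuration derives slope and wavelength", {
  cfg <- radar_config()
  expect_equal(cfg$slope * cfg$T_chirp, cfg$B)
  expect_equal(cfg$wavelength, 299792458 / 77e9)
  expect_error(radar_config(B = -1), "B")
})
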