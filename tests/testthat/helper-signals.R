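# Shared helpers for building test signals and reading spectra.

test_time <- function(fs = 20, duration = 60) {
  (seq_len(round(fs * duration)) - 1) / fs
}

# Frequency of the largest Hann-windowed spectral magnitude inside a band.
peak_freq <- function(x, fs, band, n_fft = 4096) {
  spectral_peak(x, fs, band, n_fft = n_fft)$frequency
}

# Spectral energy (raw periodogram) inside a band.
band_power <- function(x, fs, band) {
  n <- length(x)
  spec <- Mod(stats::fft(x))^2 / n
  freq <- (seq_len(n) - 1) * fs / n
  sum(spec[freq >= band[1] & freq <= band[2] & freq <= fs / 2])
}

# The package's reference simulated phase signal.
standard_phase <- function(seed) {
  simulate_vital_phase(rng_seed = seed)
}

# Two-target scene: vital subject at 0.65 m plus strong static clutter.
clutter_scene <- function(n_frames = 1200, noise_scale = 0,
                          seed = 11L) {
  cfg <- radar_config()
  fs <- 1 / cfg$frame_period
  d <- simulate_displacement(
    vital_sign_params(harmonics = default_harmonics()),
    fs = fs, duration = n_frames / fs)
  list(
    config = cfg,
    displacement = d,
    vital_range = 0.65,
    static_range = 1.30,
    cube = simulate_if_cube(cfg, list(
      scene_target(0.65, "vital", displacement = d),
      scene_target(1.30, "static", reflectivity = 2)),
      n_frames = n_frames, noise_scale = noise_scale,
      rng_seed = seed))
}
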