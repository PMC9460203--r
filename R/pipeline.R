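# End-to-end orchestration: cube -> clutter filter -> range FFT -> bin
# selection -> DACM phase -> adaptive EEMD -> rates.

#' Run the full vital-sign pipeline
#'
#' Executes the processing chain on either an IF data cube (full radar
#' path) or a phase signal (decomposition path only): static clutter
#' filter, range FFT, target-bin selection, DACM phase extraction,
#' optional phase differencing, adaptive alpha-stable EEMD, and rate
#' estimation by autocorrelation (headline), spectral peak and peak
#' counting.
#'
#' @param cube An [if_cube()], or `NULL` when `phase` is given.
#' @param phase A [phase_signal()]; skips the radar stages.
#' @param config An [eemd_config()].
#' @param bands A [vital_bands()].
#' @param radar A [radar_config()] (annotation for reports; taken from
#'   the cube when present).
#' @param use_phase_difference Decompose the differenced phase instead of
#'   the raw phase? Default `FALSE`: the reference decompositions operate
#'   on the original time-varying phase.
#' @param n_fft Range-FFT length (cube path only).
#' @return List of class `vitals_report`: `bin` (selected range bin, or
#'   `NA` on the phase path), `range_m`, `phase`, `decomposition` (an
#'   `imf_set`), `rates` (data frame: component, method, frequency_hz,
#'   rate_per_min, flag), and `seed`.
#' @examples
#' \donttest{
#' sim <- simulate_vital_phase(rng_seed = 2)
#' rep <- run_pipeline(phase = sim$phase,
#'                     config = eemd_config(n_ensemble = 20))
#' rep$rates
#' }
#' @export
run_pipeline <- function(cube = NULL, phase = NULL,
                         config = eemd_config(), bands = vital_bands(),
                         radar = NULL, use_phase_difference = FALSE,
                         n_fft = NULL) {
  if (is.null(cube) && is.null(phase)) {
    stop("supply either an IF cube or a phase signal", call. = FALSE)
  }
  bin <- NA_integer_
  range_m <- NA_real_
  if (!is.null(cube)) {
    stopifnot(inherits(cube, "if_cube"))
    radar <- cube$config
    filtered <- static_clutter_filter(cube)
    profiles <- range_fft(filtered, n_fft = n_fft)
    bin <- select_target_bin(profiles)
    range_m <- (bin - 1L) * profiles$bin_spacing
    phase <- dacm_phase(iq_at_bin(profiles, bin))
  }
  stopifnot(inherits(phase, "phase_signal"))
  work <- if (use_phase_difference) phase_difference(phase) else phase
  fit <- improved_eemd(work$samples, config, bands, fs = work$fs)
  rates <- pipeline_rates(fit, bands)
  structure(list(bin = bin, range_m = range_m, phase = phase,
                 decomposition = fit, rates = rates,
                 seed = config$rng_seed),
            class = "vitals_report")
}

pipeline_rates <- function(fit, bands) {
  one <- function(q, band, comp) {
    if (is.null(q)) return(NULL)
    imf <- fit$imfs[[q]]
    fs <- fit$fs
    ests <- list(
      tryCatch(rate_from_autocorr(autocorrelation(imf), fs, band, comp),
               error = function(e) NULL),
      spectral_peak(imf, fs, band, component = comp),
      rate_from_peaks(imf, fs, component = comp))
    do.call(rbind, lapply(ests, function(e) {
      if (is.null(e)) return(NULL)
      data.frame(component = e$component, method = e$method,
                 frequency_hz = e$frequency, rate_per_min = e$rate,
                 flag = e$flag, stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(
    one(fit$labels$respiration, bands$breath_freq, "respiration"),
    one(fit$labels$heartbeat, bands$heart_freq, "heartbeat"))
  if (is.null(out)) {
    out <- data.frame(component = character(0), method = character(0),
                      frequency_hz = numeric(0),
                      rate_per_min = numeric(0), flag = character(0))
  }
  out
}

#' @export
print.vitals_report <- function(x, ...) {
  cat("<vitals_report>\n")
  if (!is.na(x$bin)) {
    cat(sprintf("  target bin %d (%.2f m)\n", x$bin, x$range_m))
  }
  cat(sprintf("  %d IMFs, terminated early: %s\n",
              length(x$decomposition$imfs),
              x$decomposition$terminated_early))
  print(x$rates)
  invisible(x)
}

#' Generate the package's reference fixtures
#'
#' Writes three deterministic synthetic data sets with ground-truth JSON
#' sidecars: (1) the standard simulated 60 s phase signal (respiration
#' 0.32 Hz plus harmonics 2/3/4/6, heartbeat 1.54 Hz); (2) an IF cube of
#' a vital target plus a static clutter target; (3) a 250 s phase signal
#' whose heart rate ramps from 1.2 to 1.4 Hz for streaming tests. The
#' same seed reproduces every file byte for byte.
#'
#' @param seed Integer seed.
#' @param out_dir Writable output directory (created if missing).
#' @return Manifest data frame (`file`, `md5`), invisibly written as
#'   `manifest.csv` too.
#' @export
make_fixtures <- function(seed, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2L) != 0L) {
    stop(sprintf("'%s' is not writable", out_dir), call. = FALSE)
  }
  seed <- as.integer(seed)
  paths <- character(0)

  # (1) standard simulated phase signal
  sim <- simulate_vital_phase(rng_seed = seed)
  p1 <- file.path(out_dir, "phase_standard.csv")
  write_phase_csv(sim$phase, p1)
  jsonlite::write_json(
    list(f_re = 0.32, f_hr = 1.54, fs = 20, duration = 60,
         harmonics = c(2, 3, 4, 6), noise_scale = 0.2, seed = seed),
    file.path(out_dir, "phase_standard.truth.json"),
    auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p1, file.path(out_dir, "phase_standard.truth.json"))

  # (2) vital target + static clutter IF cube (64 frames keeps it small)
  cfg <- radar_config()
  n_frames <- 64L
  d <- simulate_displacement(
    vital_sign_params(harmonics = default_harmonics()),
    fs = 1 / cfg$frame_period, duration = n_frames * cfg$frame_period)
  cube <- simulate_if_cube(cfg, list(
    scene_target(0.65, "vital", displacement = d),
    scene_target(1.30, "static", reflectivity = 2)),
    n_frames = n_frames, noise_scale = 0.01, rng_seed = seed + 1L)
  p2 <- file.path(out_dir, "scene_cube.bin")
  write_if_cube(cube, p2)
  truth_bin <- round(0.65 / range_resolution(cfg$B)) + 1L
  jsonlite::write_json(
    list(vital_range_m = 0.65, static_range_m = 1.30,
         vital_bin = truth_bin, n_frames = n_frames, seed = seed + 1),
    file.path(out_dir, "scene_cube.truth.json"),
    auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p2, file.path(out_dir, "scene_cube.truth.json"))

  # (3) 250 s streaming phase signal with a slow heart-rate ramp
  fs <- 20
  t <- (0:(250 * fs - 1)) / fs
  f0 <- 1.2
  f1 <- 1.4
  finst <- f0 + (f1 - f0) * t / max(t)
  lam <- SPEED_OF_LIGHT / 77e9
  disp <- 4e-3 * cos(2 * pi * 0.32 * t) +
    4e-4 * cos(2 * pi * cumsum(finst) / fs)
  ph <- add_noise(4 * pi / lam * disp, 0.2, "gaussian",
                  rng_seed = seed + 2L)
  p3 <- file.path(out_dir, "phase_stream.csv")
  write_phase_csv(phase_signal(ph, fs), p3)
  jsonlite::write_json(
    list(f_re = 0.32, f_hr_start = f0, f_hr_end = f1, fs = fs,
         duration = 250, seed = seed + 2),
    file.path(out_dir, "phase_stream.truth.json"),
    auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p3, file.path(out_dir, "phase_stream.truth.json"))

  manifest <- data.frame(file = basename(paths),
                         md5 = vapply(paths, function(p) {
                           as.character(tools::md5sum(p))
                         }, character(1)),
                         row.names = NULL)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
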