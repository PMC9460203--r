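# Synthetic vital-sign scenes: chest displacement, phase signals, and
# complex IF data cubes, so the whole processing chain runs without radar
# hardware.

#' Vital-sign displacement parameters
#'
#' Chest displacement is modelled as a heartbeat tone plus a respiration
#' tone plus a set of respiration harmonics,
#' \deqn{x(t) = A_{hr}\cos(2\pi f_{hr} t + \varphi_{hr}) +
#'   A_{re}\cos(2\pi f_{re} t + \varphi_{re}) +
#'   \sum_m A_m \cos(2\pi m f_{re} t + \varphi_m).}
#' Respiratory chest motion is roughly an order of magnitude larger than
#' heartbeat motion (millimetres vs tenths of a millimetre), and its
#' harmonics fall inside the heart band — the separation problem this
#' package addresses.
#'
#' @param A_re,f_re,phi_re Respiration amplitude (m), frequency (Hz), phase
#'   (rad).
#' @param A_hr,f_hr,phi_hr Heartbeat amplitude (m), frequency (Hz), phase
#'   (rad).
#' @param harmonics Data frame with columns `m` (integer order >= 2), `A`
#'   (amplitude, m), `phi` (rad); harmonic `m` oscillates at `m * f_re`.
#' @return Object of class `vital_sign_params`.
#' @examples
#' vital_sign_params(f_re = 0.32, f_hr = 1.54)
#' @export
vital_sign_params <- function(A_re = 4e-3, f_re = 0.32, phi_re = 0,
                              A_hr = 4e-4, f_hr = 1.54, phi_hr = 0,
                              harmonics = data.frame(m = integer(0),
                                                     A = numeric(0),
                                                     phi = numeric(0))) {
  vals <- c(A_re, f_re, phi_re, A_hr, f_hr, phi_hr,
            harmonics$m, harmonics$A, harmonics$phi)
  if (!all(is.finite(vals))) {
    stop("vital-sign parameters must be finite", call. = FALSE)
  }
  stopifnot(A_re >= 0, A_hr >= 0, f_re >= 0, f_hr >= 0)
  if (A_hr > 0 && A_re > 0 && A_re <= A_hr) {
    stop("respiration amplitude must exceed heartbeat amplitude",
         call. = FALSE)
  }
  if (f_re > 0 && f_hr > 0 && f_re >= f_hr) {
    stop("respiration frequency must be below heartbeat frequency",
         call. = FALSE)
  }
  if (nrow(harmonics)) {
    stopifnot(all(harmonics$m >= 2), !anyDuplicated(harmonics$m),
              all(harmonics$m == round(harmonics$m)))
  }
  structure(list(A_re = A_re, f_re = f_re, phi_re = phi_re,
                 A_hr = A_hr, f_hr = f_hr, phi_hr = phi_hr,
                 harmonics = harmonics),
            class = "vital_sign_params")
}

#' Default respiration-harmonic table
#'
#' Harmonic orders 2, 3, 4 and 6 of the respiration fundamental, with
#' amplitudes decaying as `A_re / m^2` — the decay rate of the Fourier
#' coefficients of a smooth, continuous periodic motion. Under this decay
#' the 3rd harmonic (which falls in the heart band) has phase amplitude
#' comparable to the heartbeat tone itself, the regime in which harmonic
#' interference genuinely threatens heart-rate estimation while remaining
#' physically separable.
#'
#' @param A_re Respiration amplitude (m).
#' @param orders Integer harmonic orders.
#' @param decay Power-law decay exponent of the harmonic amplitudes.
#' @return Data frame suitable for [vital_sign_params()]'s `harmonics`.
#' @export
default_harmonics <- function(A_re = 4e-3, orders = c(2L, 3L, 4L, 6L),
                              decay = 2) {
  data.frame(m = as.integer(orders), A = A_re / orders^decay,
             phi = rep(0, length(orders)))
}

component_frequencies <- function(params) {
  c(params$f_hr, params$f_re, params$harmonics$m * params$f_re)
}

#' Simulate chest displacement
#'
#' @param params A [vital_sign_params()].
#' @param fs Sample rate (Hz); must exceed twice the highest component
#'   frequency.
#' @param duration Length of the series (s).
#' @return Numeric displacement series in metres, length
#'   `round(duration * fs)`, sampled at `t = 0, 1/fs, ...`.
#' @examples
#' x <- simulate_displacement(vital_sign_params(), fs = 20, duration = 60)
#' @export
simulate_displacement <- function(params, fs, duration) {
  stopifnot(inherits(params, "vital_sign_params"), fs > 0, duration > 0)
  fmax <- max(component_frequencies(params), 0)
  if (fs <= 2 * fmax) {
    stop(sprintf(
      "fs = %g Hz aliases the %g Hz component; need fs > %g Hz",
      fs, fmax, 2 * fmax), call. = FALSE)
  }
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  x <- params$A_hr * cos(2 * pi * params$f_hr * t + params$phi_hr) +
    params$A_re * cos(2 * pi * params$f_re * t + params$phi_re)
  h <- params$harmonics
  for (i in seq_len(nrow(h))) {
    x <- x + h$A[i] * cos(2 * pi * h$m[i] * params$f_re * t + h$phi[i])
  }
  x
}

#' Phase-signal container
#'
#' @param samples Numeric phase samples (rad).
#' @param fs Slow-time sample rate (Hz).
#' @param t0 Start time (s).
#' @return Object of class `phase_signal`.
#' @export
phase_signal <- function(samples, fs, t0 = 0) {
  stopifnot(is.numeric(samples), length(samples) >= 2L, fs > 0)
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = "phase_signal")
}

#' @export
print.phase_signal <- function(x, ...) {
  cat(sprintf("<phase_signal> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Map displacement to radar phase
#'
#' A target at radial distance `R + D(t)` imposes the two-way carrier
#' phase `psi(t) = (4 pi / lambda) (D(t) + R)` on the IF signal.
#'
#' @param displacement Displacement series (m).
#' @param wavelength Carrier wavelength (m).
#' @param R Nominal target range (m).
#' @param fs Sample rate of the series (Hz).
#' @return A [phase_signal()] in radians.
#' @export
displacement_to_phase <- function(displacement, wavelength, R = 0,
                                  fs = 20) {
  stopifnot(wavelength > 0, all(is.finite(displacement)))
  phase_signal(4 * pi / wavelength * (displacement + R), fs = fs)
}

#' Add seeded noise to a series
#'
#' @param signal Numeric series.
#' @param scale Noise scale. With `relative = TRUE` (default) the noise
#'   standard scale is `scale * sd(signal)` — the convention used for the
#'   simulated phase signals, where a "noise ratio" of 0.2 means noise at
#'   20% of the signal's standard deviation. With `relative = FALSE` it is
#'   an absolute scale.
#' @param kind `"gaussian"` or `"alpha_stable"`.
#' @param alpha Stability index for alpha-stable noise, in (0, 2].
#' @param rng_seed Integer seed for bit-for-bit reproducibility.
#' @param relative Interpret `scale` relative to `sd(signal)`?
#' @return `signal` plus noise. `scale = 0` returns the input unchanged.
#'   Alpha-stable noise uses dispersion `scale / sqrt(2)` so that
#'   `alpha = 2` reduces exactly to Gaussian noise of standard deviation
#'   `scale`.
#' @export
add_noise <- function(signal, scale, kind = c("gaussian", "alpha_stable"),
                      alpha = 1.5, rng_seed = NULL, relative = TRUE) {
  kind <- match.arg(kind)
  if (scale < 0) stop("noise scale must be nonnegative", call. = FALSE)
  if (scale == 0) return(signal)
  s <- if (relative) scale * stats::sd(signal) else scale
  n <- length(signal)
  if (kind == "gaussian") {
    if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
    noise <- stats::rnorm(n, sd = s)
  } else {
    noise <- sample_alpha_stable(n, alpha, scale = s / sqrt(2),
                                 rng_seed = rng_seed)
  }
  signal + noise
}

#' The standard simulated vital-sign phase signal
#'
#' Convenience generator for the package's reference simulation: a
#' respiration fundamental at 0.32 Hz with 2nd/3rd/4th/6th harmonics, a
#' heartbeat tone at 1.54 Hz, sampled at 20 Hz for 60 s, converted to
#' phase at the 77 GHz carrier wavelength, with additive Gaussian noise at
#' 0.2 of the clean signal's standard deviation.
#'
#' @param fs Sample rate (Hz).
#' @param duration Duration (s).
#' @param f_re,f_hr Respiration and heartbeat frequencies (Hz).
#' @param noise_scale Noise ratio relative to the clean phase standard
#'   deviation.
#' @param wavelength Carrier wavelength (m).
#' @param rng_seed Integer seed.
#' @return List with `phase` (a [phase_signal()]), `displacement` (clean
#'   series, m), `clean_phase` (noiseless phase samples, rad), and
#'   `params`.
#' @examples
#' sim <- simulate_vital_phase(rng_seed = 1)
#' sim$phase
#' @export
simulate_vital_phase <- function(fs = 20, duration = 60, f_re = 0.32,
                                 f_hr = 1.54, noise_scale = 0.2,
                                 wavelength = SPEED_OF_LIGHT / 77e9,
                                 rng_seed = 1L) {
  params <- vital_sign_params(f_re = f_re, f_hr = f_hr,
                              harmonics = default_harmonics())
  d <- simulate_displacement(params, fs = fs, duration = duration)
  clean <- 4 * pi / wavelength * d
  noisy <- add_noise(clean, noise_scale, kind = "gaussian",
                     rng_seed = rng_seed)
  list(phase = phase_signal(noisy, fs = fs), displacement = d,
       clean_phase = clean, params = params)
}

#' Scene target for IF-cube simulation
#'
#' @param range Radial distance R from the radar (m).
#' @param motion `"static"`, `"vital"` (displacement series supplied), or
#'   `"linear"` (constant radial velocity).
#' @param displacement Numeric displacement series (m), one value per
#'   frame, required for `motion = "vital"`.
#' @param velocity Radial velocity (m/s) for `motion = "linear"`.
#' @param reflectivity Relative amplitude.
#' @return Object of class `scene_target`.
#' @export
scene_target <- function(range, motion = c("static", "vital", "linear"),
                         displacement = NULL, velocity = 0,
                         reflectivity = 1) {
  motion <- match.arg(motion)
  stopifnot(range > 0, reflectivity > 0)
  if (motion == "vital" && is.null(displacement)) {
    stop("vital targets need a displacement series", call. = FALSE)
  }
  structure(list(range = range, motion = motion,
                 displacement = displacement, velocity = velocity,
                 reflectivity = reflectivity),
            class = "scene_target")
}

#' Complex IF data cube container
#'
#' @param data Complex matrix, frames (slow time) by fast-time samples.
#' @param config A [radar_config()].
#' @return Object of class `if_cube`.
#' @export
if_cube <- function(data, config) {
  stopifnot(is.matrix(data), nrow(data) >= 1L,
            inherits(config, "radar_config"),
            all(is.finite(Re(data))), all(is.finite(Im(data))))
  structure(list(data = data, config = config), class = "if_cube")
}

#' @export
print.if_cube <- function(x, ...) {
  cat(sprintf("<if_cube> %d frames x %d fast-time samples\n",
              nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Simulate a complex IF data cube
#'
#' Each frame's fast-time row is the coherent sum over targets of the
#' post-mixing single-tone model: a complex exponential at beat frequency
#' `f_b = 2 * slope * r / c` carrying the two-way carrier phase
#' `(4 pi / lambda) r`, where `r` is the target's instantaneous range at
#' that frame. Static targets contribute identical rows every frame.
#'
#' @param config A [radar_config()].
#' @param targets List of [scene_target()]s (at least one).
#' @param n_frames Number of slow-time frames L.
#' @param noise_scale Standard deviation of additive complex white noise
#'   (absolute, relative to unit reflectivity); 0 for noiseless.
#' @param rng_seed Integer seed.
#' @return An [if_cube()].
#' @examples
#' cube <- simulate_if_cube(radar_config(),
#'   list(scene_target(1.0)), n_frames = 4)
#' @export
simulate_if_cube <- function(config, targets, n_frames,
                             noise_scale = 0, rng_seed = NULL) {
  stopifnot(inherits(config, "radar_config"), n_frames >= 1L)
  if (length(targets) == 0L) {
    stop("need at least one scene target", call. = FALSE)
  }
  rmax <- max_range(config)
  t_fast <- (seq_len(config$n_samples) - 1) / config$adc_rate
  t_slow <- (seq_len(n_frames) - 1) * config$frame_period
  data <- matrix(0 + 0i, n_frames, config$n_samples)
  for (tg in targets) {
    r <- switch(tg$motion,
      static = rep(tg$range, n_frames),
      linear = tg$range + tg$velocity * t_slow,
      vital = {
        d <- tg$displacement
        if (length(d) < n_frames) {
          stop("displacement series shorter than n_frames", call. = FALSE)
        }
        tg$range + d[seq_len(n_frames)]
      })
    if (any(r <= 0) || any(r >= rmax)) {
      stop(sprintf("target range outside (0, %.2f m)", rmax),
           call. = FALSE)
    }
    fb <- 2 * config$slope * r / SPEED_OF_LIGHT
    psi <- 4 * pi / config$wavelength * r
    # outer product: rows are frames, columns fast time
    data <- data + tg$reflectivity *
      exp(1i * (2 * pi * outer(fb, t_fast) + psi))
  }
  if (noise_scale > 0) {
    if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
    n <- length(data)
    data <- data + noise_scale / sqrt(2) *
      (stats::rnorm(n) + 1i * stats::rnorm(n))
  }
  if_cube(data, config)
}
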