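# Radar configuration and derived quantities.

SPEED_OF_LIGHT <- 299792458

#' FMCW radar chirp/frame configuration
#'
#' Collects the chirp parameters of a sawtooth FMCW radar and derives the
#' chirp slope and carrier wavelength. Defaults correspond to a 77 GHz
#' automotive-band sensor sweeping 4 GHz in a 60 microsecond chirp with 256
#' fast-time samples and a 20 Hz frame (slow-time) rate.
#'
#' @param fc Carrier start frequency (Hz).
#' @param B Sweep bandwidth (Hz).
#' @param T_chirp Chirp duration (s).
#' @param frame_period Slow-time sampling interval Tr (s).
#' @param n_samples Fast-time samples per chirp.
#' @param adc_rate Fast-time sample rate (Hz); defaults to
#'   `n_samples / T_chirp` so the whole chirp is sampled.
#' @return Object of class `radar_config` with fields `fc`, `B`, `T_chirp`,
#'   `slope`, `frame_period`, `n_samples`, `adc_rate`, `wavelength`.
#' @examples
#' cfg <- radar_config()
#' cfg$wavelength # about 3.9 mm at 77 GHz
#' @export
radar_config <- function(fc = 77e9, B = 4e9, T_chirp = 60e-6,
                         frame_period = 1 / 20, n_samples = 256L,
                         adc_rate = n_samples / T_chirp) {
  stopifnot(fc > 0, B > 0, T_chirp > 0, frame_period > 0,
            n_samples >= 1, adc_rate > 0)
  slope <- B / T_chirp
  structure(list(fc = fc, B = B, T_chirp = T_chirp, slope = slope,
                 frame_period = frame_period,
                 n_samples = as.integer(n_samples), adc_rate = adc_rate,
                 wavelength = SPEED_OF_LIGHT / fc),
            class = "radar_config")
}

#' @export
print.radar_config <- function(x, ...) {
  cat(sprintf(paste0("<radar_config> fc = %.3g GHz, B = %.3g GHz, ",
                     "slope = %.3g MHz/us\n  frame rate = %.3g Hz, ",
                     "%d samples/chirp, lambda = %.3g mm\n"),
              x$fc / 1e9, x$B / 1e9, x$slope / 1e12,
              1 / x$frame_period, x$n_samples, x$wavelength * 1e3))
  invisible(x)
}

#' Range resolution of an FMCW radar
#'
#' The minimum separable radial distance, `c / (2 B)`.
#'
#' @param B Sweep bandwidth (Hz).
#' @return Range resolution in metres (0.0375 m for B = 4 GHz).
#' @export
range_resolution <- function(B) {
  stopifnot(B > 0)
  SPEED_OF_LIGHT / (2 * B)
}

#' Unambiguous (maximum) range for a configuration
#'
#' Beat frequencies are identifiable up to the fast-time Nyquist rate,
#' giving `adc_rate * c / (4 * slope)`.
#'
#' @param config A [radar_config()].
#' @return Maximum unambiguous range in metres.
#' @export
max_range <- function(config) {
  config$adc_rate * SPEED_OF_LIGHT / (4 * config$slope)
}
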