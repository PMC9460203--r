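# Respiration / heart-rate estimation from labeled IMFs.

new_rate_estimate <- function(frequency, method, component,
                              flag = NA_character_) {
  structure(list(frequency = frequency, rate = 60 * frequency,
                 method = method, component = component, flag = flag),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %s: %.3f Hz = %.1f per minute (%s)%s\n",
              x$component, x$frequency, x$rate, x$method,
              if (is.na(x$flag)) "" else paste0(" [", x$flag, "]")))
  invisible(x)
}

#' Normalized autocorrelation
#'
#' Biased-normalized autocorrelation with `R(0) = 1`, computed via FFT
#' (zero-padded to avoid circular wrap-around), for lags `0 .. n-1`.
#'
#' @param x Numeric series, length >= 4, nonzero variance.
#' @return Numeric vector of length `length(x)`.
#' @export
autocorrelation <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 4L)
  x <- x - mean(x)
  if (all(x == 0)) {
    stop("zero-variance input has no autocorrelation structure",
         call. = FALSE)
  }
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n))
  sp <- stats::fft(c(x, rep(0, nfft - n)))
  r <- Re(stats::fft(sp * Conj(sp), inverse = TRUE))[seq_len(n)]
  r / r[1]
}

#' Rate from the autocorrelation peak
#'
#' Finds the highest local maximum of the autocorrelation at lags
#' corresponding to periods inside the frequency band; the reciprocal of
#' that lag is the rate. Ties break to the lowest lag.
#'
#' @param R Autocorrelation series (from [autocorrelation()]).
#' @param fs Sample rate (Hz).
#' @param band `c(fmin, fmax)` admissible frequency band (Hz), inside
#'   `(0, fs/2)`.
#' @param component `"respiration"` or `"heartbeat"` (annotation only).
#' @param min_peak Peaks below this autocorrelation value are reported
#'   with a `"weak periodicity"` flag (aperiodic inputs such as white
#'   noise rarely exceed it).
#' @return A `rate_estimate`; errors when no local maximum exists in the
#'   admissible lag window.
#' @export
rate_from_autocorr <- function(R, fs, band,
                               component = c("heartbeat",
                                             "respiration"),
                               min_peak = 0.2) {
  component <- match.arg(component)
  stopifnot(band[1] > 0, band[2] > band[1], band[2] < fs / 2)
  lag_min <- max(2L, floor(fs / band[2]))
  lag_max <- min(length(R) - 1L, ceiling(fs / band[1]))
  if (lag_max <= lag_min) {
    stop("band leaves no admissible autocorrelation lags",
         call. = FALSE)
  }
  # local maxima within the lag window
  ext <- find_extrema(R)$maxima - 1L # to 0-based lags
  ext <- ext[ext >= lag_min & ext <= lag_max]
  if (!length(ext)) {
    stop("no autocorrelation peak in band: no periodicity detected",
         call. = FALSE)
  }
  best <- ext[which.max(R[ext + 1L])]
  new_rate_estimate(fs / best, "autocorr", component,
                    flag = if (R[best + 1L] < min_peak) {
                      "weak periodicity"
                    } else {
                      NA_character_
                    })
}

#' Rate by counting IMF peaks
#'
#' `rate = Tminute * Rnumpeaks * fs / LSize`, where `Rnumpeaks` counts
#' strict local maxima of the IMF over its `LSize` samples.
#'
#' @param imf Numeric IMF samples, at least `fs` of them (>= 1 s).
#' @param fs Sample rate (Hz).
#' @param Tminute Reporting duration (s); 60 gives per-minute rates.
#' @param component Annotation.
#' @return A `rate_estimate` (rate field in events per `Tminute`);
#'   zero peaks yield rate 0 with flag `"no peaks"`.
#' @export
rate_from_peaks <- function(imf, fs, Tminute = 60,
                            component = c("heartbeat", "respiration")) {
  component <- match.arg(component)
  stopifnot(length(imf) >= fs)
  npk <- length(find_extrema(imf)$maxima)
  rate <- Tminute * npk * fs / length(imf)
  out <- new_rate_estimate(rate / 60, "peak_count", component,
                           flag = if (npk == 0) "no peaks" else NA)
  out
}

#' Rate from the spectral peak in a band
#'
#' Hann-windowed, zero-padded FFT; returns the frequency of the largest
#' magnitude bin inside the band.
#'
#' @param imf Numeric series.
#' @param fs Sample rate (Hz).
#' @param band `c(fmin, fmax)` (Hz).
#' @param n_fft FFT length; default gives bin spacing <= 0.01 Hz.
#' @param component Annotation.
#' @return A `rate_estimate`.
#' @export
spectral_peak <- function(imf, fs, band,
                          n_fft = 2^ceiling(log2(max(length(imf),
                                                     fs / 0.01))),
                          component = c("heartbeat", "respiration")) {
  component <- match.arg(component)
  n <- length(imf)
  stopifnot(n_fft >= n, band[2] > band[1])
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  sp <- Mod(stats::fft(c(imf * w, rep(0, n_fft - n))))
  freq <- (seq_len(n_fft) - 1) * fs / n_fft
  sel <- which(freq >= band[1] & freq <= band[2] & freq <= fs / 2)
  if (!length(sel)) stop("empty frequency band", call. = FALSE)
  new_rate_estimate(freq[sel[which.max(sp[sel])]], "spectral", component)
}

#' Root-mean-square error between rate sequences
#'
#' @param estimates,references Equal-length numeric vectors.
#' @return `sqrt(mean((estimates - references)^2))`.
#' @export
rmse <- function(estimates, references) {
  if (length(estimates) != length(references)) {
    stop("estimate and reference sequences differ in length",
         call. = FALSE)
  }
  stopifnot(length(estimates) >= 1L)
  sqrt(mean((estimates - references)^2))
}

#' Sliding-window vital-rate estimation
#'
#' Applies [improved_eemd()] plus rate estimation to overlapping windows
#' of a phase signal, emulating streaming operation. Each window's
#' estimate is timestamped at the window end; the per-window RNG seed is
#' derived as `rng_seed + window index` so that results are reproducible
#' and translation-invariant for aligned windows.
#'
#' @param phase A [phase_signal()].
#' @param window Window length (s).
#' @param step Hop between windows (s).
#' @param config An [eemd_config()].
#' @param bands A [vital_bands()].
#' @param method Rate estimator for the headline numbers: `"autocorr"`
#'   (default), `"spectral"`, or `"peak_count"`.
#' @return Data frame with one row per window: `time` (s, window end),
#'   `respiration_hz`, `respiration_bpm`, `heart_hz`, `heart_bpm`,
#'   `method`, `flag`.
#' @export
stream_process <- function(phase, window, step, config = eemd_config(),
                           bands = vital_bands(),
                           method = c("autocorr", "spectral",
                                      "peak_count")) {
  method <- match.arg(method)
  stopifnot(inherits(phase, "phase_signal"), step > 0)
  fs <- phase$fs
  n <- length(phase$samples)
  wlen <- round(window * fs)
  hop <- round(step * fs)
  if (wlen > n) stop("window longer than the signal", call. = FALSE)
  starts <- seq(1L, n - wlen + 1L, by = hop)
  short_window <- window < 1 / bands$breath_freq[1]
  rows <- lapply(seq_along(starts), function(i) {
    seg <- phase$samples[starts[i]:(starts[i] + wlen - 1L)]
    cfg <- config
    cfg$rng_seed <- config$rng_seed + i
    fit <- improved_eemd(seg, cfg, bands, fs = fs)
    est <- function(q, band, comp) {
      if (is.null(q)) return(NULL)
      imf <- fit$imfs[[q]]
      tryCatch(switch(method,
        autocorr = rate_from_autocorr(autocorrelation(imf), fs, band,
                                      comp),
        spectral = spectral_peak(imf, fs, band, component = comp),
        peak_count = rate_from_peaks(imf, fs, component = comp)),
        error = function(e) NULL)
    }
    hb <- est(fit$labels$heartbeat, bands$heart_freq, "heartbeat")
    re <- est(fit$labels$respiration, bands$breath_freq, "respiration")
    flag <- if (short_window) {
      "window shorter than one respiration period"
    } else {
      fit$warning
    }
    data.frame(
      time = phase$t0 + (starts[i] + wlen - 1L) / fs,
      respiration_hz = if (is.null(re)) NA_real_ else re$frequency,
      respiration_bpm = if (is.null(re)) NA_real_ else re$rate,
      heart_hz = if (is.null(hb)) NA_real_ else hb$frequency,
      heart_bpm = if (is.null(hb)) NA_real_ else hb$rate,
      method = method,
      flag = if (is.null(flag)) NA_character_ else flag,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
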