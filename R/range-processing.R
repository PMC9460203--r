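# Static clutter filtering, range FFT, and target-bin selection.

#' Static clutter filter (slow-time mean subtraction)
#'
#' Stationary reflectors contribute the same fast-time samples in every
#' frame, while a periodic vital signal averages towards zero over whole
#' cycles. Subtracting the across-frame mean from every fast-time column
#' therefore nulls static clutter and leaves periodic motion intact.
#'
#' @param cube An [if_cube()] with at least two frames.
#' @return A filtered [if_cube()]; every fast-time column has zero mean
#'   across frames.
#' @export
static_clutter_filter <- function(cube) {
  stopifnot(inherits(cube, "if_cube"))
  if (nrow(cube$data) < 2L) {
    stop("need at least two frames to estimate the clutter mean",
         call. = FALSE)
  }
  avg <- colMeans(cube$data)
  if_cube(sweep(cube$data, 2L, avg), cube$config)
}

#' Range FFT over fast time
#'
#' @param cube An [if_cube()].
#' @param n_fft FFT length; defaults to the next power of two at or above
#'   the number of fast-time samples. Must be >= `n_samples`.
#' @param window `"none"` (default, bit-exact peaks for pure tones) or
#'   `"hann"`.
#' @return Object of class `range_profile_set`: list with `profiles`
#'   (complex matrix, frames x bins), `bin_spacing` (m/bin), `config`.
#' @export
range_fft <- function(cube, n_fft = NULL, window = c("none", "hann")) {
  stopifnot(inherits(cube, "if_cube"))
  window <- match.arg(window)
  ns <- ncol(cube$data)
  if (is.null(n_fft)) n_fft <- 2^ceiling(log2(ns))
  if (n_fft < ns) {
    stop("n_fft must be at least the number of fast-time samples",
         call. = FALSE)
  }
  x <- cube$data
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ns) - 1) / (ns - 1))
    x <- sweep(x, 2L, w, `*`)
  }
  if (n_fft > ns) {
    x <- cbind(x, matrix(0 + 0i, nrow(x), n_fft - ns))
  }
  profiles <- t(apply(x, 1L, stats::fft))
  if (nrow(cube$data) == 1L) profiles <- matrix(profiles, nrow = 1L)
  bin_spacing <- range_resolution(cube$config$B) * ns / n_fft
  structure(list(profiles = profiles, bin_spacing = bin_spacing,
                 config = cube$config),
            class = "range_profile_set")
}

#' @export
print.range_profile_set <- function(x, ...) {
  cat(sprintf("<range_profile_set> %d frames x %d bins (%.4f m/bin)\n",
              nrow(x$profiles), ncol(x$profiles), x$bin_spacing))
  invisible(x)
}

#' Slow-time variance per range bin
#'
#' @param profiles A `range_profile_set`.
#' @return Numeric vector of complex slow-time variances per bin.
#' @export
bin_variances <- function(profiles) {
  p <- profiles$profiles
  ctr <- sweep(p, 2L, colMeans(p))
  colMeans(Mod(ctr)^2)
}

#' Select the vital-target range bin
#'
#' After clutter filtering the subject is the bin whose complex value
#' varies most over slow time, so the selection statistic is the slow-time
#' variance, not magnitude. Ties break to the lowest bin index.
#'
#' @param profiles A `range_profile_set` (clutter-filtered).
#' @return 1-based bin index.
#' @export
select_target_bin <- function(profiles) {
  v <- bin_variances(profiles)
  if (all(v == 0)) {
    stop("all range bins have zero slow-time variance: no target",
         call. = FALSE)
  }
  unname(which.max(v)) # which.max takes the first (lowest) maximum
}

#' Slow-time complex series at one range bin
#'
#' @param profiles A `range_profile_set`.
#' @param bin 1-based bin index.
#' @return Complex vector, one value per frame.
#' @export
bin_slow_time <- function(profiles, bin) {
  stopifnot(bin >= 1L, bin <= ncol(profiles$profiles))
  profiles$profiles[, bin]
}
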