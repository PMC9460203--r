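# Empirical mode decomposition: sifting with cubic-spline envelopes.

#' Locate strict local extrema of a series
#'
#' Strict local maxima and minima over three points; plateaus are resolved
#' to their first sample so that counting is deterministic.
#'
#' @param x Numeric vector.
#' @return List with integer index vectors `maxima` and `minima`.
#' @keywords internal
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) {
    return(list(maxima = integer(0), minima = integer(0)))
  }
  dx <- diff(x)
  # carry the previous nonzero slope across plateaus so a flat-topped peak
  # counts once, at its first sample
  s <- sign(dx)
  nz <- s != 0
  if (!any(nz)) {
    return(list(maxima = integer(0), minima = integer(0)))
  }
  idx <- cumsum(nz)
  filled <- s
  filled[idx > 0L] <- s[nz][idx[idx > 0L]]
  ds <- diff(filled)
  maxima <- which(ds == -2) + 1L
  minima <- which(ds == 2) + 1L
  list(maxima = maxima, minima = minima)
}

# Cubic-spline envelope through extrema with mirrored boundary extrema.
# Mirrors up to two edge extrema about each end point (standard sifting
# boundary treatment) to tame end swings.
envelope_spline <- function(idx, val, n) {
  k <- length(idx)
  m <- min(2L, k)
  pre_i <- 2L - idx[seq_len(m)]           # reflect about sample 1
  pre_v <- val[seq_len(m)]
  post_i <- 2L * n - idx[k - seq_len(m) + 1L]  # reflect about sample n
  post_v <- val[k - seq_len(m) + 1L]
  xi <- c(rev(pre_i), idx, rev(post_i))
  yi <- c(rev(pre_v), val, rev(post_v))
  keep <- !duplicated(xi)
  stats::spline(xi[keep], yi[keep], xout = seq_len(n), method = "fmm")$y
}

# Mean of upper and lower cubic-spline envelopes; NULL when there are not
# enough extrema on either side to sift further.
envelope_mean <- function(x, ext = find_extrema(x)) {
  if (length(ext$maxima) < 2L || length(ext$minima) < 2L) {
    return(NULL)
  }
  n <- length(x)
  upper <- envelope_spline(ext$maxima, x[ext$maxima], n)
  lower <- envelope_spline(ext$minima, x[ext$minima], n)
  (upper + lower) / 2
}

# Extract one intrinsic mode function from x by sifting.
# Stops when the Cauchy criterion sum((h0-h1)^2)/sum(h0^2) drops below
# sd_threshold or after sift_max iterations. The stop rule is the Cauchy
# criterion alone: over-sifting to force the exact extrema/zero-crossing
# balance on noisy input smears physically distinct tones across modes.
sift_imf <- function(x, sift_max = 10L, sd_threshold = 0.2) {
  h <- x
  for (i in seq_len(sift_max)) {
    m <- envelope_mean(h)
    if (is.null(m)) {
      break
    }
    h1 <- h - m
    denom <- sum(h^2)
    if (denom == 0) {
      h <- h1
      break
    }
    sd_c <- sum((h - h1)^2) / denom
    h <- h1
    if (sd_c < sd_threshold) {
      break
    }
  }
  h
}

n_interior_extrema <- function(x) {
  ext <- find_extrema(x)
  length(ext$maxima) + length(ext$minima)
}

#' Configuration for EMD / EEMD decompositions
#'
#' @param n_ensemble Ensemble size `I`. For the alpha-stable adaptive EEMD
#'   this counts antithetic pairs (each draw is used with both signs), so
#'   `2 * n_ensemble` perturbed decompositions enter every stage mean.
#' @param Nstd Ensemble noise scale as a fraction of the standard deviation
#'   of the analysed signal.
#' @param noise_kind `"gaussian"` or `"alpha_stable"`.
#' @param alpha Stability index of the symmetric alpha-stable ensemble
#'   noise, in (0, 2]; `alpha = 2` is Gaussian.
#' @param sift_max Maximum sifting iterations per mode.
#' @param sift_sd_threshold Cauchy stopping threshold for sifting.
#' @param rng_seed Integer seed; all randomness in a decomposition flows
#'   from it.
#' @param adaptive_termination Stop decomposition once a mode satisfies the
#'   respiration-band extrema-rate and amplitude criteria
#'   (see [termination_check()]).
#' @param max_imf Hard cap on the number of modes (safety net; the natural
#'   stop is a residual with fewer than two interior extrema).
#' @return An object of class `eemd_config`.
#' @export
eemd_config <- function(n_ensemble = 100L, Nstd = 0.2,
                        noise_kind = c("alpha_stable", "gaussian"),
                        alpha = 1.5, sift_max = 10L,
                        sift_sd_threshold = 0.2, rng_seed = 42L,
                        adaptive_termination = TRUE, max_imf = 20L) {
  noise_kind <- match.arg(noise_kind)
  stopifnot(n_ensemble >= 1L, Nstd >= 0, sift_max >= 1L,
            sift_sd_threshold > 0, max_imf >= 1L)
  if (alpha <= 0 || alpha > 2) {
    stop("`alpha` must lie in (0, 2]", call. = FALSE)
  }
  structure(list(n_ensemble = as.integer(n_ensemble), Nstd = Nstd,
                 noise_kind = noise_kind, alpha = alpha,
                 sift_max = as.integer(sift_max),
                 sift_sd_threshold = sift_sd_threshold,
                 rng_seed = as.integer(rng_seed),
                 adaptive_termination = isTRUE(adaptive_termination),
                 max_imf = as.integer(max_imf)),
            class = "eemd_config")
}

new_imf_set <- function(imfs, residual, fs, diagnostics = NULL,
                        labels = list(), stages = length(imfs),
                        terminated_early = FALSE, warning = NULL) {
  structure(list(imfs = imfs, residual = residual, fs = fs,
                 diagnostics = diagnostics, labels = labels,
                 stages = stages, terminated_early = terminated_early,
                 warning = warning),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMF(s) + residual, n = %d, fs = %g Hz\n",
              length(x$imfs), length(x$residual), x$fs))
  if (!is.null(x$labels$respiration)) {
    cat(sprintf("  respiration: IMF%d\n", x$labels$respiration))
  }
  if (!is.null(x$labels$heartbeat)) {
    cat(sprintf("  heartbeat:   IMF%d\n", x$labels$heartbeat))
  }
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Empirical mode decomposition
#'
#' Decomposes a series into intrinsic mode functions (IMFs) plus a residual
#' by iterative sifting with cubic-spline envelopes. Decomposition continues
#' while the running residual still has at least two interior extrema; a
#' monotone input therefore yields zero IMFs and a residual equal to the
#' input.
#'
#' @param signal Numeric vector, length >= 8.
#' @param config An [eemd_config()]; only the sifting fields are used.
#' @param fs Sample rate in Hz (carried into the result for labeling and
#'   spectral diagnostics).
#' @return An object of class `imf_set` with elements `imfs` (list of
#'   numeric vectors), `residual`, `fs`.
#' @examples
#' x <- sin(2 * pi * 3 * seq(0, 60, by = 0.02)) +
#'   sin(2 * pi * 0.3 * seq(0, 60, by = 0.02))
#' fit <- emd(x, eemd_config(), fs = 50)
#' length(fit$imfs)
#' @export
emd <- function(signal, config = eemd_config(), fs = 1) {
  stopifnot(is.numeric(signal), length(signal) >= 8L,
            all(is.finite(signal)))
  residual <- as.numeric(signal)
  imfs <- list()
  while (length(imfs) < config$max_imf &&
         n_interior_extrema(residual) >= 2L) {
    imf <- sift_imf(residual, config$sift_max, config$sift_sd_threshold)
    if (all(imf == 0)) break
    imfs[[length(imfs) + 1L]] <- imf
    residual <- residual - imf
  }
  new_imf_set(imfs, residual, fs)
}
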