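# Readers/writers for IF data cubes, phase series, and scene configs.

IFCUBE_MAGIC <- "IFCB"

#' Write an IF data cube to a binary file
#'
#' Little-endian layout: 4-byte magic `"IFCB"`, `L` and `n_samples` as
#' 32-bit integers, then `fc`, `B`, `T_chirp`, `frame_period`, `adc_rate`
#' as 64-bit floats, then the samples as interleaved float32 I,Q pairs in
#' frame-major order. Round-trips losslessly at float32 precision.
#'
#' @param cube An [if_cube()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_if_cube <- function(cube, path) {
  stopifnot(inherits(cube, "if_cube"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(IFCUBE_MAGIC, con, nchars = 4L, eos = NULL)
  writeBin(c(nrow(cube$data), ncol(cube$data)), con, size = 4L,
           endian = "little")
  cfg <- cube$config
  writeBin(c(cfg$fc, cfg$B, cfg$T_chirp, cfg$frame_period,
             cfg$adc_rate), con, size = 8L, endian = "little")
  m <- t(cube$data) # frame-major on disk
  interleaved <- as.vector(rbind(Re(as.vector(m)), Im(as.vector(m))))
  writeBin(interleaved, con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an IF data cube written by [write_if_cube()]
#'
#' @param path File path.
#' @return An [if_cube()] (sample values at float32 precision).
#' @export
read_if_cube <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(magic, IFCUBE_MAGIC)) {
    stop(sprintf("'%s' is not an IF-cube file (bad magic)", path),
         call. = FALSE)
  }
  dims <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  hdr <- readBin(con, "numeric", 5L, size = 8L, endian = "little")
  n <- dims[1] * dims[2]
  iq <- readBin(con, "numeric", 2L * n, size = 4L, endian = "little")
  z <- complex(real = iq[c(TRUE, FALSE)], imaginary = iq[c(FALSE, TRUE)])
  cfg <- radar_config(fc = hdr[1], B = hdr[2], T_chirp = hdr[3],
                      frame_period = hdr[4], n_samples = dims[2],
                      adc_rate = hdr[5])
  if_cube(matrix(z, nrow = dims[1], ncol = dims[2], byrow = TRUE), cfg)
}

#' Write an IF data cube as CSV
#'
#' One frame per row, alternating I,Q columns (`i1,q1,i2,q2,...`), full
#' double precision.
#'
#' @param cube An [if_cube()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_if_cube_csv <- function(cube, path) {
  stopifnot(inherits(cube, "if_cube"))
  L <- nrow(cube$data)
  ns <- ncol(cube$data)
  out <- matrix(0, L, 2L * ns)
  out[, c(TRUE, FALSE)] <- Re(cube$data)
  out[, c(FALSE, TRUE)] <- Im(cube$data)
  colnames(out) <- paste0(rep(c("i", "q"), ns),
                          rep(seq_len(ns), each = 2L))
  utils::write.csv(as.data.frame(out), path, row.names = FALSE)
  invisible(path)
}

#' Read a CSV IF data cube
#'
#' @param path File path (layout of [write_if_cube_csv()]).
#' @param config A [radar_config()] describing the capture.
#' @return An [if_cube()].
#' @export
read_if_cube_csv <- function(path, config) {
  m <- as.matrix(utils::read.csv(path))
  z <- complex(real = m[, c(TRUE, FALSE), drop = FALSE],
               imaginary = m[, c(FALSE, TRUE), drop = FALSE])
  if_cube(matrix(z, nrow = nrow(m)), config)
}

#' Write a phase signal as CSV
#'
#' Columns `time`, `phase`, and (when `diff = TRUE`) `phase_diff`.
#'
#' @param phase A [phase_signal()].
#' @param path Output file path.
#' @param diff Include the first-difference column?
#' @return `path`, invisibly.
#' @export
write_phase_csv <- function(phase, path, diff = TRUE) {
  stopifnot(inherits(phase, "phase_signal"))
  n <- length(phase$samples)
  df <- data.frame(
    time = phase$t0 + (seq_len(n) - 1) / phase$fs,
    phase = phase$samples)
  if (diff) df$phase_diff <- c(NA, base::diff(phase$samples))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a phase-signal CSV
#'
#' @param path File path with `time` and `phase` columns.
#' @return A [phase_signal()]; the sample rate is inferred from the
#'   median time step.
#' @export
read_phase_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time", "phase") %in% names(df)))
  dt <- stats::median(base::diff(df$time))
  phase_signal(df$phase, fs = 1 / dt, t0 = df$time[1])
}

#' Write decomposition results
#'
#' CSV with one column per IMF plus the residual, and a JSON sidecar with
#' per-IMF diagnostics, labels, stage count and termination status.
#'
#' @param imfset An `imf_set`.
#' @param path CSV path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_imf_set <- function(imfset, path) {
  stopifnot(inherits(imfset, "imf_set"))
  cols <- c(imfset$imfs, list(imfset$residual))
  names(cols) <- c(sprintf("imf%d", seq_along(imfset$imfs)), "residual")
  utils::write.csv(as.data.frame(cols), path, row.names = FALSE)
  meta <- list(fs = imfset$fs, stages = imfset$stages,
               terminated_early = imfset$terminated_early,
               labels = imfset$labels, warning = imfset$warning,
               diagnostics = imfset$diagnostics)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a scene/radar configuration from YAML or JSON
#'
#' Top-level keys `radar` (fields of [radar_config()]), `targets` (list
#' of [scene_target()] field sets), and optionally `eemd` (fields of
#' [eemd_config()]).
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return List with `radar`, `targets`, `eemd` elements.
#' @export
read_scene_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file '%s' does not exist", path),
         call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  # YAML without a signed exponent ("7.7e10") parses as character; coerce
  # anything that reads as a number back to numeric
  renumber <- function(l) {
    lapply(l, function(v) {
      if (is.character(v) && length(v) == 1L) {
        nv <- suppressWarnings(as.numeric(v))
        if (!is.na(nv)) return(nv)
      }
      v
    })
  }
  radar <- do.call(radar_config, renumber(as.list(raw$radar %||%
                                                   list())))
  targets <- lapply(raw$targets %||% list(), function(t) {
    do.call(scene_target, renumber(as.list(t)))
  })
  eemd_cfg <- do.call(eemd_config, renumber(as.list(raw$eemd %||%
                                                      list())))
  list(radar = radar, targets = targets, eemd = eemd_cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
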