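#' Auditory white-noise specification
#'
#' Stereo uniform noise: each channel is an independent stream of integers
#' drawn uniformly on `[0, max_value]`, affinely mapped onto the symmetric
#' 16-bit sample range and written as uncompressed PCM WAV. The default
#' `max_value` of 225 reproduces the study's printed distribution bound
#' verbatim; pass 255 for the full 8-bit range if that bound is suspected to
#' be a typo (see the methods vignette).
#'
#' @param duration_s noise duration in seconds.
#' @param sample_rate_hz audio sample rate (default 48,000).
#' @param channels number of channels (default 2, independent streams).
#' @param bit_depth bits per sample (only 16 is supported).
#' @param max_value upper bound of the uniform integer distribution.
#' @param seed optional integer seed.
#' @return An object of class `audio_noise_spec`.
#' @export
audio_noise_spec <- function(duration_s, sample_rate_hz = 48000,
                             channels = 2, bit_depth = 16, max_value = 225,
                             seed = NULL) {
  stopifnot(duration_s > 0, sample_rate_hz > 0, channels >= 1,
            bit_depth == 16, max_value >= 1)
  structure(list(duration_s = duration_s, sample_rate_hz = sample_rate_hz,
                 channels = channels, bit_depth = bit_depth,
                 max_value = max_value, seed = seed),
            class = "audio_noise_spec")
}

#' Generate a uniform auditory white-noise WAV file
#'
#' @param spec an [audio_noise_spec()].
#' @param path output `.wav` path.
#' @return invisibly, the integer sample matrix (frames x channels) that was
#'   written.
#' @export
generate_auditory_noise <- function(spec, path) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- round(spec$duration_s * spec$sample_rate_hz)
  raw <- matrix(sample.int(spec$max_value + 1L, n * spec$channels,
                           replace = TRUE) - 1L,
                nrow = n, ncol = spec$channels)
  # affine map [0, max] -> [-32767, 32767]
  mapped <- matrix(as.integer(round(raw * (65534 / spec$max_value) - 32767)),
                   nrow = n)
  write_wav(mapped, spec$sample_rate_hz, path)
  invisible(mapped)
}

#' Minimal uncompressed PCM WAV writer / reader
#'
#' 16-bit little-endian PCM only; `samples` is an integer matrix with one
#' column per channel, values in `[-32768, 32767]`.
#'
#' @param samples integer frame-by-channel matrix.
#' @param rate sample rate in Hz.
#' @param path file path.
#' @return `read_wav()` a list with `samples`, `rate`, `bit_depth`.
#' @export
write_wav <- function(samples, rate, path) {
  samples <- as.matrix(samples)
  if (any(samples < -32768 | samples > 32767))
    stop("samples out of 16-bit range")
  ch <- ncol(samples)
  n <- nrow(samples)
  data_bytes <- n * ch * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(as.integer(ch), con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * ch * 2L), con, size = 4, endian = "little")
  writeBin(as.integer(ch * 2L), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(as.integer(t(samples)), con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (riff != "RIFF" || wave != "WAVE") stop("not a RIFF/WAVE file: ", path)
  rate <- NA_integer_; ch <- NA_integer_; bits <- NA_integer_
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      ch <- readBin(con, "integer", 1, size = 2, endian = "little")
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (id == "data") {
      if (bits != 16) stop("only 16-bit PCM is supported")
      vals <- readBin(con, "integer", size / 2, size = 2, endian = "little",
                      signed = TRUE)
      samples <- matrix(vals, ncol = ch, byrow = TRUE)
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  list(samples = samples, rate = rate, bit_depth = bits)
}

#' Visual pixel-noise specification
#'
#' Per-refresh blending of a stimulus frame with fresh uniform pixel noise:
#' `out = (1 - alpha) * image + alpha * noise`, so `alpha = 0` leaves the
#' stimulus unchanged and `alpha = 1` yields pure noise. Pixel values live on
#' `[0, max_value]` where 0 is black and `max_value` white; the study levels
#' are `alpha = 0.25` and `0.50` at 60 Hz.
#'
#' @param alpha transparency level of the noise layer, in `[0, 1]`.
#' @param refresh_hz screen refresh rate (frames per second).
#' @param max_value upper pixel bound (printed study value 225; see
#'   [audio_noise_spec()]).
#' @param seed optional integer seed.
#' @return An object of class `visual_noise_spec`.
#' @export
visual_noise_spec <- function(alpha, refresh_hz = 60, max_value = 225,
                              seed = NULL) {
  stopifnot(alpha >= 0, alpha <= 1, refresh_hz > 0, max_value >= 1)
  structure(list(alpha = alpha, refresh_hz = refresh_hz,
                 max_value = max_value, seed = seed),
            class = "visual_noise_spec")
}

#' Blend a stimulus frame with per-refresh pixel noise
#'
#' @param image numeric matrix (grayscale frame) with values on
#'   `[0, max_value]`.
#' @param spec a [visual_noise_spec()].
#' @param duration_s duration; frame count is `ceiling(duration * refresh)`.
#' @param n_frames frame count given directly (overrides `duration_s`).
#' @return list of blended frames (numeric matrices), fresh noise per frame.
#' @export
blend_visual_noise <- function(image, spec, duration_s = NULL,
                               n_frames = NULL) {
  image <- as.matrix(image)
  if (any(image < 0 | image > spec$max_value))
    stop("image values must lie on [0, max_value]")
  if (is.null(n_frames)) {
    if (is.null(duration_s)) stop("give duration_s or n_frames")
    n_frames <- ceiling(duration_s * spec$refresh_hz)
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  lapply(seq_len(n_frames), function(i) {
    noise <- matrix(sample.int(spec$max_value + 1L, length(image),
                               replace = TRUE) - 1L,
                    nrow = nrow(image))
    (1 - spec$alpha) * image + spec$alpha * noise
  })
}

#' Write noise frames as PNG files
#'
#' @param frames list of frames from [blend_visual_noise()].
#' @param dir output directory.
#' @param max_value pixel scale used to normalize to `[0, 1]`.
#' @return character vector of written paths, invisibly.
#' @export
write_noise_frames <- function(frames, dir, max_value = 225) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("writing PNG frames needs the `png` package")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(frames), function(i) {
    p <- file.path(dir, sprintf("frame%04d.png", i))
    png::writePNG(pmin(pmax(frames[[i]] / max_value, 0), 1), p)
    p
  }, character(1))
  invisible(paths)
}
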