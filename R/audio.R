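#' Construct an audio signal object
#'
#' A light container for a mono waveform: amplitude samples (dimensionless,
#' within [-1, 1] after normalization), the sampling rate in Hz, and the
#' derived duration in seconds.
#'
#' @param samples numeric vector of amplitudes.
#' @param sample_rate sampling rate in Hz (> 0).
#' @return object of class `audio_signal` with fields `samples`,
#'   `sample_rate`, `duration`.
#' @export
audio_signal <- function(samples, sample_rate) {
  stopifnot(is.numeric(samples), length(samples) > 0L,
            is.numeric(sample_rate), sample_rate > 0)
  structure(
    list(samples = as.numeric(samples),
         sample_rate = as.numeric(sample_rate),
         duration = length(samples) / sample_rate),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %.3f s @ %g Hz (peak %.3f)\n",
              x$duration, x$sample_rate, max(abs(x$samples))))
  invisible(x)
}

#' Load, downmix, resample and normalize an audio recording
#'
#' Reads a PCM (or float32) WAV file, averages channels to mono, resamples to
#' `target_rate` by linear interpolation, and peak-normalizes the amplitude to
#' 1 (a digitally silent file is left at zero rather than divided by zero).
#'
#' @param path path to a WAV file.
#' @param target_rate output sampling rate in Hz; the pipeline standard is
#'   16000.
#' @return an [audio_signal()].
#' @export
load_audio <- function(path, target_rate = 16000) {
  w <- read_wav(path)
  x <- if (w$n_channels > 1L) colMeans(w$samples) else as.numeric(w$samples)
  if (length(x) == 0L) stop("zero-length audio signal: ", path)
  x <- resample_linear(x, w$sample_rate, target_rate)
  peak <- max(abs(x))
  if (peak > 0) x <- x / peak
  audio_signal(x, target_rate)
}

# Linear-interpolation resampler; preserves duration to within one output
# sample period. Output length n_out = round(n_in * to / from).
resample_linear <- function(x, from, to) {
  if (from == to) return(x)
  n_in <- length(x)
  n_out <- max(1L, as.integer(round(n_in * to / from)))
  t_out <- (seq_len(n_out) - 1) / to
  t_in <- (seq_len(n_in) - 1) / from
  stats::approx(t_in, x, xout = pmin(t_out, t_in[n_in]), rule = 2)$y
}
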