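#' @title Energy-based voice activity detection
#' @description
#' Speech/pause segmentation follows the classic short-time log-energy recipe:
#' (1) log energy on 25 ms windows with a 10 ms hop, (2) DC (mean) removal,
#' (3) smoothing by convolution with a normalized Gaussian window, (4) a
#' data-driven threshold separating the silent and speech-labeled energy
#' clusters, and (5) run-length conversion of the framewise decisions into
#' segments, with segments shorter than a minimum duration merged into their
#' neighbours. Voiced rate is computed independently from an autocorrelation
#' fundamental-frequency track.
#' @name vad
NULL

LOG_ENERGY_FLOOR <- 1e-10

#' Framewise log energy
#'
#' Log of the mean squared amplitude per frame, floored at `1e-10` before the
#' log so that digital silence maps to a finite value. The last partial frame
#' is discarded.
#'
#' @param signal an [audio_signal()].
#' @param frame_len frame length in seconds (default 0.025).
#' @param hop hop size in seconds (default 0.010).
#' @return object of class `energy_trace`: `values` (log energy per frame),
#'   `frame_times` (frame centres, seconds), `frame_len`, `hop`, and the
#'   signal `duration`.
#' @export
compute_log_energy <- function(signal, frame_len = 0.025, hop = 0.010) {
  stopifnot(inherits(signal, "audio_signal"))
  sr <- signal$sample_rate
  flen <- as.integer(round(frame_len * sr))
  fhop <- as.integer(round(hop * sr))
  n <- length(signal$samples)
  if (n < flen) stop("signal shorter than one frame")
  n_frames <- (n - flen) %/% fhop + 1L
  # O(n) framing via cumulative sum of squared amplitude
  cs <- c(0, cumsum(signal$samples^2))
  starts <- (seq_len(n_frames) - 1L) * fhop + 1L
  e <- (cs[starts + flen] - cs[starts]) / flen
  structure(
    list(values = log(pmax(e, LOG_ENERGY_FLOOR)),
         frame_times = (starts - 1L + flen / 2) / sr,
         frame_len = frame_len, hop = hop,
         duration = signal$duration),
    class = "energy_trace"
  )
}

# Normalized Gaussian kernel with sigma = width/2 (seconds), truncated at
# +/- 3 sigma, expressed in frames of the trace's hop.
gaussian_kernel <- function(width, hop) {
  sigma <- (width / 2) / hop
  radius <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-0.5 * ((-radius:radius) / sigma)^2)
  k / sum(k)
}

#' Smooth a log-energy trace
#'
#' Subtracts the DC level (trace mean) and convolves with a normalized
#' Gaussian window; edges are handled by reflection so the output has the
#' same length as the input.
#'
#' @param trace an `energy_trace`.
#' @param gaussian_width Gaussian window width in seconds (default 0.010);
#'   the kernel standard deviation is half the width, truncated at 3 sigma.
#' @return an `energy_trace` with smoothed, zero-mean values.
#' @export
smooth_energy <- function(trace, gaussian_width = 0.010) {
  stopifnot(inherits(trace, "energy_trace"), length(trace$values) > 0L)
  v <- trace$values - mean(trace$values)
  k <- gaussian_kernel(gaussian_width, trace$hop)
  radius <- (length(k) - 1L) %/% 2L
  n <- length(v)
  # reflection padding (degenerate short traces fall back to edge replication)
  left <- if (n > 1L) v[pmin(n, 1L + abs(seq(-radius, -1L)))] else rep(v[1L], radius)
  right <- if (n > 1L) v[pmax(1L, n - seq_len(radius))] else rep(v[n], radius)
  padded <- c(left, v, right)
  sm <- stats::filter(padded, k, sides = 2L)
  trace$values <- as.numeric(sm[(radius + 1L):(radius + n)])
  trace
}

#' Estimate the speech/silence energy threshold
#'
#' Two-means iteration on the (smoothed) log-energy values: cluster means are
#' initialized at the 10th and 90th percentiles, frames are assigned to the
#' nearer mean, and the means are recomputed until assignment is stable. The
#' threshold is the midpoint of the converged cluster means, which lies
#' strictly between the silent-cluster and speech-cluster averages.
#'
#' @param trace an `energy_trace` (usually smoothed).
#' @return log-energy threshold (scalar).
#' @export
estimate_threshold <- function(trace) {
  stopifnot(inherits(trace, "energy_trace"))
  v <- trace$values
  if (length(v) < 2L || stats::var(v) == 0) {
    stop("energy trace has no speech/silence contrast (zero variance)")
  }
  centers <- unname(stats::quantile(v, c(0.10, 0.90), type = 7))
  if (diff(centers) == 0) centers <- range(v)
  assign_old <- rep(-1L, length(v))
  for (iter in seq_len(100L)) {
    assign_new <- as.integer(abs(v - centers[2]) < abs(v - centers[1]))
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
    if (any(assign_new == 0L)) centers[1] <- mean(v[assign_new == 0L])
    if (any(assign_new == 1L)) centers[2] <- mean(v[assign_new == 1L])
  }
  mean(centers)
}

#' Segment a recording into speech and pauses
#'
#' Frames with (smoothed) log energy above the threshold are labeled speech,
#' the rest pause; maximal runs become segments; segments shorter than
#' `min_seg` are merged into their neighbours (shortest first). Segment
#' boundaries are placed midway between adjacent frame centres, and the first
#' and last segments are extended to 0 and the recording duration, so the
#' segments tile the recording exactly.
#'
#' @param trace an `energy_trace` (usually smoothed).
#' @param threshold log-energy threshold, e.g. from [estimate_threshold()].
#' @param min_seg minimum segment duration in seconds (default 0.05).
#' @return object of class `segmentation`: a data.frame `segments` with
#'   columns `start_s`, `end_s`, `label` plus the `threshold` and `energy`
#'   trace that produced it.
#' @export
segment_speech_pause <- function(trace, threshold, min_seg = 0.05) {
  stopifnot(inherits(trace, "energy_trace"), length(trace$values) > 0L)
  lab <- ifelse(trace$values > threshold, "speech", "pause")
  r <- rle(lab)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  ft <- trace$frame_times
  n <- length(ft)
  # boundary between frame i and i+1 at the midpoint of their centres
  bound <- c(0, (ft[-n] + ft[-1]) / 2, trace$duration)
  seg <- data.frame(start_s = bound[starts_idx],
                    end_s = bound[ends_idx + 1L],
                    label = r$values, stringsAsFactors = FALSE)
  seg <- merge_short_segments(seg, min_seg)
  structure(list(segments = seg, threshold = threshold, energy = trace),
            class = "segmentation")
}

# Repeatedly relabel the shortest sub-minimum segment and fuse it with its
# (now same-labeled) neighbours, preserving the tiling and alternation
# invariants. A recording made of a single segment is left as is.
merge_short_segments <- function(seg, min_seg) {
  repeat {
    if (nrow(seg) <= 1L) break
    dur <- seg$end_s - seg$start_s
    short <- which(dur < min_seg - 1e-12)
    if (!length(short)) break
    i <- short[which.min(dur[short])]
    seg$label[i] <- if (i == 1L) seg$label[2L] else seg$label[i - 1L]
    keep <- c(TRUE, seg$label[-1L] != seg$label[-nrow(seg)])
    ends <- c(seg$start_s[which(keep)[-1]], seg$end_s[nrow(seg)])
    seg <- data.frame(start_s = seg$start_s[keep], end_s = ends,
                      label = seg$label[keep], stringsAsFactors = FALSE)
  }
  rownames(seg) <- NULL
  seg
}

#' @export
print.segmentation <- function(x, ...) {
  s <- x$segments
  cat(sprintf("<segmentation> %d segments over %.2f s (%.0f%% pause), threshold %.3f\n",
              nrow(s), max(s$end_s),
              100 * sum((s$end_s - s$start_s)[s$label == "pause"]) / max(s$end_s),
              x$threshold))
  invisible(x)
}

#' Run the full VAD chain on a signal
#'
#' Convenience wrapper: log energy, smoothing, threshold estimation (per
#' recording) and segmentation.
#'
#' @inheritParams compute_log_energy
#' @inheritParams segment_speech_pause
#' @param gaussian_width smoothing window width in seconds.
#' @return a `segmentation`.
#' @export
detect_speech <- function(signal, frame_len = 0.025, hop = 0.010,
                          gaussian_width = 0.010, min_seg = 0.05) {
  tr <- smooth_energy(compute_log_energy(signal, frame_len, hop), gaussian_width)
  segment_speech_pause(tr, estimate_threshold(tr), min_seg)
}

#' Write a segmentation as 3-column TSV
#'
#' @param seg a `segmentation`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_segments <- function(seg, path) {
  stopifnot(inherits(seg, "segmentation"))
  utils::write.table(seg$segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a 3-column segment TSV back into a `segmentation`
#'
#' @param path TSV with columns `start_s`, `end_s`, `label`.
#' @return a `segmentation` (without an energy trace).
#' @export
read_segments <- function(path) {
  seg <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("start_s", "end_s", "label") %in% names(seg)))
  segmentation_from_segments(seg)
}

# Build a `segmentation` from a bare segment table (used for precomputed /
# synthetic segmentations); validates tiling and alternation.
segmentation_from_segments <- function(seg, threshold = NA_real_) {
  stopifnot(all(seg$end_s > seg$start_s))
  if (nrow(seg) > 1L) {
    stopifnot(max(abs(seg$start_s[-1] - seg$end_s[-nrow(seg)])) < 1e-9)
  }
  structure(list(segments = seg, threshold = threshold, energy = NULL),
            class = "segmentation")
}

#' Fundamental-frequency track and voiced rate
#'
#' Estimates F0 per frame by short-time autocorrelation (FFT-based, search
#' range 60-400 Hz); a frame is voiced when its normalized autocorrelation
#' peak is at least `voicing_threshold` and its energy is above digital
#' silence. Maximal runs of voiced frames form voiced segments; the voiced
#' rate is their count divided by the recording duration.
#'
#' @param signal an [audio_signal()].
#' @param frame_len analysis window in seconds (default 0.032; long enough to
#'   hold two periods at 60 Hz search with the padded autocorrelation).
#' @param hop hop in seconds (default 0.010).
#' @param f0_min,f0_max F0 search range in Hz.
#' @param voicing_threshold normalized autocorrelation peak required to call
#'   a frame voiced (default 0.5).
#' @return list with `voicing` (class `voicing_result`: `voiced_segments`
#'   data.frame and `f0_track`, 0 = unvoiced) and `rate` (voiced segments per
#'   second).
#' @export
voiced_rate <- function(signal, frame_len = 0.032, hop = 0.010,
                        f0_min = 60, f0_max = 400, voicing_threshold = 0.5) {
  stopifnot(inherits(signal, "audio_signal"))
  sr <- signal$sample_rate
  flen <- as.integer(round(frame_len * sr))
  fhop <- as.integer(round(hop * sr))
  x <- signal$samples
  n <- length(x)
  empty <- function() {
    structure(list(voiced_segments = data.frame(start_s = numeric(0),
                                                end_s = numeric(0)),
                   f0_track = numeric(0), frame_times = numeric(0)),
              class = "voicing_result")
  }
  if (n < flen) return(list(voicing = empty(), rate = 0))
  n_frames <- (n - flen) %/% fhop + 1L
  starts <- (seq_len(n_frames) - 1L) * fhop + 1L
  idx <- outer(seq_len(flen) - 1L, starts, `+`)
  frames <- matrix(x[idx], nrow = flen)
  frames <- sweep(frames, 2L, colMeans(frames))
  nfft <- 2^ceiling(log2(2L * flen))
  padded <- rbind(frames, matrix(0, nfft - flen, n_frames))
  spec <- stats::mvfft(padded)
  ac <- Re(stats::mvfft(spec * Conj(spec), inverse = TRUE)) / nfft
  r0 <- ac[1L, ]
  lag_lo <- max(2L, as.integer(floor(sr / f0_max)))
  lag_hi <- min(flen - 1L, as.integer(ceiling(sr / f0_min)))
  band <- ac[(lag_lo + 1L):(lag_hi + 1L), , drop = FALSE]
  peak_lag <- lag_lo - 1L + apply(band, 2L, which.max)
  peak_val <- band[cbind(apply(band, 2L, which.max), seq_len(n_frames))]
  norm_peak <- ifelse(r0 > flen * LOG_ENERGY_FLOOR, peak_val / r0, 0)
  voiced <- norm_peak >= voicing_threshold
  f0 <- ifelse(voiced, sr / peak_lag, 0)
  ft <- (starts - 1L + flen / 2) / sr
  segs <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (any(voiced)) {
    r <- rle(voiced)
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    keep <- r$values
    segs <- data.frame(start_s = pmax(0, ft[s[keep]] - frame_len / 2),
                       end_s = pmin(signal$duration, ft[e[keep]] + frame_len / 2))
  }
  voicing <- structure(list(voiced_segments = segs, f0_track = f0,
                            frame_times = ft),
                       class = "voicing_result")
  list(voicing = voicing, rate = nrow(segs) / signal$duration)
}
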