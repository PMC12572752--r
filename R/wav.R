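# Minimal RIFF/WAVE reader and writer.
# No WAV package ships with the runtime image, so the subset of the format the
# pipeline needs is handled here: uncompressed PCM (8/16/24/32 bit) and IEEE
# float32, any channel count. Samples are returned as doubles scaled to [-1, 1].

read_wav <- function(path) {
  if (!file.exists(path)) stop("audio file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  readBin(con, "integer", 1L, size = 4L, endian = "little")  # chunk size
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = sum(as.integer(body[1:2]) * c(1L, 256L)),
        n_channels   = sum(as.integer(body[3:4]) * c(1L, 256L)),
        sample_rate  = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(body[15:16]) * c(1L, 256L))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)  # skip other chunks
    }
    if (size %% 2L == 1L) readBin(con, "raw", 1L)  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("incomplete WAV file: ", path)

  bytes_per <- fmt$bits %/% 8L
  n_total <- length(data_raw) %/% bytes_per
  if (n_total == 0L) stop("zero-length audio signal: ", path)

  if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "numeric", n_total, size = 4L, endian = "little")
  } else if (fmt$audio_format == 1L) {
    if (fmt$bits == 8L) {
      # 8-bit WAV is unsigned
      x <- (as.integer(data_raw[seq_len(n_total)]) - 128) / 128
    } else if (fmt$bits %in% c(16L, 32L)) {
      x <- readBin(data_raw, "integer", n_total, size = bytes_per,
                   signed = TRUE, endian = "little") / 2^(fmt$bits - 1)
    } else if (fmt$bits == 24L) {
      b <- as.integer(data_raw)
      i1 <- seq(1L, by = 3L, length.out = n_total)
      v <- b[i1] + b[i1 + 1L] * 256L + b[i1 + 2L] * 65536L
      v <- ifelse(v >= 2^23, v - 2^24, v)
      x <- v / 2^23
    } else stop("unsupported PCM bit depth: ", fmt$bits)
  } else {
    stop("unsupported WAV encoding (format tag ", fmt$audio_format, ")")
  }

  nch <- max(1L, fmt$n_channels)
  n_frames <- length(x) %/% nch
  x <- matrix(x[seq_len(n_frames * nch)], nrow = nch)
  list(samples = x, sample_rate = fmt$sample_rate, n_channels = nch)
}

# `samples`: numeric vector (mono) or channels-by-frames matrix.
write_wav <- function(samples, sample_rate, path, bits = 16L) {
  stopifnot(bits == 16L)
  nch <- if (is.matrix(samples)) nrow(samples) else 1L
  x <- pmax(-1, pmin(1, as.vector(samples)))  # column-major = interleaved
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(pcm) * 2L
  block <- nch * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")          # PCM
  writeBin(nch, con, size = 2L, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate * block), con, size = 4L, endian = "little")
  writeBin(block, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")         # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
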