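sr <- 16000

test_that("log energy matches a direct per-frame summation oracle", {
  t <- (0:(sr - 1)) / sr
  sig <- audio_signal(sin(2 * pi * 440 * t), sr)
  tr <- compute_log_energy(sig)
  expect_length(tr$values, 98L)  # floor((16000-400)/160)+1
  # independent per-frame loop
  oracle <- sapply(seq_along(tr$values), function(j) {
    a <- (j - 1) * 160 + 1
    log(max(mean(sig$samples[a:(a + 399)]^2), 1e-10))
  })
  expect_lt(max(abs(tr$values - oracle)), 1e-9)
  expect_equal(diff(tr$frame_times), rep(0.010, 97L), tolerance = 1e-12)
})

test_that("digital silence hits the energy floor and short signals error", {
  z <- audio_signal(rep(0, sr), sr)
  tr <- compute_log_energy(z)
  expect_true(all(tr$values == log(1e-10)))
  expect_error(compute_log_energy(audio_signal(rep(0.1, 100), sr)),
               "shorter than one frame")
})

test_that("smoothing removes DC and equals brute-force convolution", {
  sig <- audio_signal(rnorm(sr), sr)
  tr <- compute_log_energy(sig)
  # constant trace -> all zero after DC removal
  const <- tr; const$values <- rep(3.7, length(tr$values))
  expect_equal(smooth_energy(const)$values, rep(0, length(tr$values)),
               tolerance = 1e-12)
  # arbitrary trace vs direct discrete convolution with reflected edges
  sm <- smooth_energy(tr, gaussian_width = 0.030)
  sigma <- 0.015 / 0.010
  radius <- ceiling(3 * sigma)
  k <- exp(-0.5 * ((-radius:radius) / sigma)^2); k <- k / sum(k)
  v <- tr$values - mean(tr$values)
  n <- length(v)
  pad <- c(v[1 + abs((-radius):(-1))], v, v[n - seq_len(radius)])
  oracle <- sapply(seq_len(n), function(i)
    sum(pad[i:(i + 2 * radius)] * k))
  expect_lt(max(abs(sm$values - oracle)), 1e-9)
  expect_equal(sum(k), 1, tolerance = 1e-12)
})

test_that("threshold lies between clusters and matches a two-means oracle", {
  tr <- structure(list(values = c(rep(-10, 60), rep(0, 40)),
                       frame_times = (0:99) * 0.01 + 0.0125,
                       frame_len = 0.025, hop = 0.01, duration = 1.015),
                  class = "energy_trace")
  th <- estimate_threshold(tr)
  expect_gt(th, -10); expect_lt(th, 0)

  const <- tr; const$values <- rep(1, 100)
  expect_error(estimate_threshold(const), "zero variance")

  set.seed(5)
  vals <- c(rnorm(300, -8, 0.8), rnorm(200, -1, 0.6))
  tr$values <- vals; tr$frame_times <- seq_along(vals) * 0.01
  # independent two-means iteration from the same 10/90 percentile init
  ctr <- unname(quantile(vals, c(0.1, 0.9), type = 7))
  repeat {
    a <- abs(vals - ctr[2]) < abs(vals - ctr[1])
    new_ctr <- c(mean(vals[!a]), mean(vals[a]))
    if (isTRUE(all.equal(new_ctr, ctr, tolerance = 1e-12))) break
    ctr <- new_ctr
  }
  expect_equal(estimate_threshold(tr), mean(ctr), tolerance = 1e-9)
})

test_that("segmentation tiles the recording, alternates labels, merges runts", {
  sig <- audio_signal(rnorm(2 * sr, sd = 0.2), sr)
  tr <- smooth_energy(compute_log_energy(sig))
  # all-above and all-below degenerate cases
  one_speech <- segment_speech_pause(tr, min(tr$values) - 1)
  expect_equal(one_speech$segments$label, "speech")
  expect_equal(one_speech$segments$end_s, sig$duration)
  one_pause <- segment_speech_pause(tr, max(tr$values) + 1)
  expect_equal(one_pause$segments$label, "pause")

  seg <- segment_speech_pause(tr, median(tr$values), min_seg = 0.05)
  s <- seg$segments
  expect_equal(sum(s$end_s - s$start_s), sig$duration, tolerance = 1e-9)
  expect_equal(s$start_s[-1], s$end_s[-nrow(s)], tolerance = 1e-12)
  if (nrow(s) > 1) expect_true(all(s$label[-1] != s$label[-nrow(s)]))
  expect_true(all(s$end_s - s$start_s >= 0.05 - 1e-9 | nrow(s) == 1))
})

test_that("planted boundaries are recovered and scaling does not move them", {
  set.seed(9)
  plant <- rep(c(1, 0.5), 4)  # 1 s speech / 0.5 s pause alternation
  lab <- rep(c(TRUE, FALSE), 4)
  x <- unlist(lapply(seq_along(plant), function(i) {
    n <- round(plant[i] * sr)
    if (lab[i]) 0.5 * (2 * (((1:n) / sr * 120) %% 1) - 1) + rnorm(n, sd = 0.02)
    else rnorm(n, sd = 0.02)
  }))
  sig <- audio_signal(x, sr)
  seg <- detect_speech(sig)
  planted_bounds <- cumsum(plant)[-length(plant)]
  got <- seg$segments$start_s[-1]
  err <- sapply(planted_bounds, function(b) min(abs(got - b)))
  # boundary placement is quantized by the 25 ms analysis window; half a
  # window is the attainable resolution
  expect_true(all(err <= 0.0125 + 1e-9))

  scaled <- audio_signal(x / 4, sr)
  seg2 <- detect_speech(scaled)
  expect_equal(seg2$segments$start_s, seg$segments$start_s, tolerance = 1e-9)
  expect_equal(seg2$segments$label, seg$segments$label)
})

test_that("segment TSV round-trips", {
  sig <- audio_signal(rnorm(sr, sd = 0.1), sr)
  seg <- detect_speech(sig)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_segments(seg, path)
  back <- read_segments(path)
  expect_equal(back$segments$start_s, seg$segments$start_s, tolerance = 1e-6)
  expect_equal(back$segments$label, seg$segments$label)
})

test_that("voiced rate: noise 0, sustained sawtooth 1, two bursts 2", {
  set.seed(11)
  noise <- audio_signal(rnorm(2 * sr, sd = 0.3), sr)
  expect_equal(voiced_rate(noise)$rate, 0)

  t <- (0:(sr - 1)) / sr
  saw <- audio_signal(2 * ((t * 120) %% 1) - 1, sr)
  vs <- voiced_rate(saw)
  expect_equal(nrow(vs$voicing$voiced_segments), 1L)
  expect_equal(vs$rate, 1)
  f0 <- vs$voicing$f0_track
  expect_lt(abs(median(f0[f0 > 0]) - 120), 5)

  burst <- 2 * (((1:(sr / 2)) / sr * 150) %% 1) - 1
  x <- c(burst, rnorm(sr / 2, sd = 0.05), burst, rnorm(sr / 2, sd = 0.05))
  two <- voiced_rate(audio_signal(x, sr))
  expect_equal(nrow(two$voicing$voiced_segments), 2L)
  expect_equal(two$rate, 1)  # 2 segments / 2 s
})
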