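#' @title Speech-timing features
#' @description
#' Whole-recording features are ratios and six-moment summaries over the
#' speech/pause segmentation (pause duration ratio, speech segment duration
#' ratio, pause ratio, pause-duration and speech-segment-duration statistics,
#' voiced rate). Word-level features are (normalized) word durations and
#' (normalized) word counts over token categories: all words, stop words,
#' content words, other words, the stop+content union, and a per-syllable
#' duration proxy. Feature names follow the stable scheme
#' `timing__<base>[__<category>][__<stat>]`.
#' @name timing_features
NULL

TIMING_CATEGORIES <- c("all", "stop", "content", "other", "stop_content",
                       "syllables")

#' Whole-recording timing features
#'
#' @param seg a `segmentation` tiling the recording.
#' @param voicing_rate voiced segments per second (from [voiced_rate()]), or
#'   `NA` when no audio is available.
#' @return named numeric vector of `timing__*` features. Ratios:
#'   `pause_duration_ratio` and `speech_segment_duration_ratio` are time
#'   fractions of the recording (they sum to 1); `pause_ratio` is the count
#'   of pause segments over the total segment count. Pause and
#'   speech-segment durations each get the six [summary_stats()].
#' @export
whole_recording_features <- function(seg, voicing_rate = NA_real_) {
  stopifnot(inherits(seg, "segmentation"))
  s <- seg$segments
  if (nrow(s) == 0L) stop("empty segmentation")
  dur <- s$end_s - s$start_s
  total <- sum(dur)
  is_pause <- s$label == "pause"
  pause_time <- sum(dur[is_pause])
  out <- c(
    timing__pause_duration_ratio = pause_time / total,
    timing__speech_segment_duration_ratio = 1 - pause_time / total,
    timing__pause_ratio = sum(is_pause) / nrow(s)
  )
  stat_block <- function(x, base) {
    st <- if (length(x)) summary_stats(x) else
      c(mean = NA_real_, sd = NA_real_, skewness = NA_real_,
        kurtosis = NA_real_, min = NA_real_, max = NA_real_)
    stats::setNames(st, paste0("timing__", base, "__", names(st)))
  }
  c(out,
    stat_block(dur[is_pause], "pause_duration"),
    stat_block(dur[!is_pause], "speech_segment_duration"),
    timing__voiced_rate = voicing_rate)
}

# Token rows belonging to a named category.
select_category <- function(tokens, category) {
  switch(category,
    all = tokens,
    stop = tokens[tokens$is_stop, , drop = FALSE],
    content = tokens[tokens$is_content, , drop = FALSE],
    other = tokens[!tokens$is_stop & !tokens$is_content, , drop = FALSE],
    stop_content = tokens[tokens$is_stop | tokens$is_content, , drop = FALSE],
    syllables = tokens,
    stop("unknown token category: ", category)
  )
}

#' Word-level timing features for one token category
#'
#' For the selected tokens: `word_duration` is the six-moment summary of
#' token durations (offset - onset), `normalized_word_duration` the summary
#' of duration per syllable, `word_count` the token count, and
#' `normalized_word_count` the count per second of speech time (from the
#' segmentation). The `syllables` category expands each token into
#' `n_syllables` pseudo-syllables of equal duration and summarizes those;
#' its normalized-duration block is absent (already per-syllable).
#' An empty category yields `NA` markers, never zeros.
#'
#' @param transcript an [aligned_transcript()].
#' @param seg a `segmentation` (supplies total speech time).
#' @param category one of `"all"`, `"stop"`, `"content"`, `"other"`,
#'   `"stop_content"`, `"syllables"`.
#' @return named numeric vector of `timing__*__<category>*` features.
#' @export
word_level_features <- function(transcript, seg, category = "all") {
  stopifnot(inherits(transcript, "aligned_transcript"),
            inherits(seg, "segmentation"),
            category %in% TIMING_CATEGORIES)
  s <- seg$segments
  speech_time <- sum((s$end_s - s$start_s)[s$label == "speech"])
  tok <- select_category(transcript$tokens, category)
  nm <- function(base, stat = NULL) {
    paste0("timing__", base, "__", category,
           if (!is.null(stat)) paste0("__", stat))
  }
  na6 <- c(mean = NA_real_, sd = NA_real_, skewness = NA_real_,
           kurtosis = NA_real_, min = NA_real_, max = NA_real_)
  if (nrow(tok) == 0L) {
    out <- c(stats::setNames(na6, nm("word_duration", names(na6))),
             stats::setNames(na6, nm("normalized_word_duration", names(na6))),
             stats::setNames(NA_real_, nm("word_count")),
             stats::setNames(NA_real_, nm("normalized_word_count")))
    return(out)
  }
  dur <- tok$offset_s - tok$onset_s
  if (category == "syllables") {
    per_syl <- rep(dur / tok$syllables, times = tok$syllables)
    st <- summary_stats(per_syl)
    c(stats::setNames(st, nm("word_duration", names(st))),
      stats::setNames(length(per_syl), nm("word_count")),
      stats::setNames(
        if (speech_time > 0) length(per_syl) / speech_time else NA_real_,
        nm("normalized_word_count")))
  } else {
    st <- summary_stats(dur)
    stn <- summary_stats(dur / tok$syllables)
    c(stats::setNames(st, nm("word_duration", names(st))),
      stats::setNames(stn, nm("normalized_word_duration", names(stn))),
      stats::setNames(nrow(tok), nm("word_count")),
      stats::setNames(
        if (speech_time > 0) nrow(tok) / speech_time else NA_real_,
        nm("normalized_word_count")))
  }
}

#' All timing features for one recording
#'
#' @param transcript an [aligned_transcript()].
#' @param seg a `segmentation`.
#' @param voicing_rate voiced segments per second, or `NA`.
#' @param categories token categories to include.
#' @return named numeric feature vector (modality prefix `timing__`).
#' @export
timing_features <- function(transcript, seg, voicing_rate = NA_real_,
                            categories = TIMING_CATEGORIES) {
  c(whole_recording_features(seg, voicing_rate),
    unlist(lapply(categories, function(cat)
      word_level_features(transcript, seg, cat))))
}
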