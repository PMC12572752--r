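#' @title Synthetic two-group, two-language cohorts
#' @description
#' Generates picture-description-like cohorts of patients and controls in
#' which every quantity the pipeline measures is planted by construction:
#' alternating speech/pause segment structure whose silence fraction rises
#' with a latent severity variable; transcripts whose part-of-speech mixture,
#' hypernym depth (granularity) distribution, and embedding-walk mixing
#' (semantic variability) differ by group; MMSE scores linearly tied to
#' severity; and optionally synthesized audio (amplitude-modulated sawtooth
#' speech bursts over low-level noise) so the acoustic front end can be
#' exercised end-to-end. A second "language" cohort can share the timing
#' effect while having its lexico-semantic effect directions independently
#' re-randomized and a disjoint embedding table, emulating the asymmetric
#' cross-language transfer of timing vs lexico-semantic markers.
#' @name synthetic_data
NULL

#' Cohort generator configuration
#'
#' Defaults state the emulated world: source-cohort group sizes 58 patients /
#' 59 controls, a control silence fraction of 0.30 rising to about 0.45 in
#' patients, latent severity N(0, 0.3) in controls and N(1, 0.3) in patients,
#' and MMSE = 27 - 6 x severity + N(0, 2) clipped to \[0, 30\] (patient mean
#' near 21, control mean near 27). Effect multipliers scale the
#' patient-control differences; setting one to 0 removes that group effect
#' entirely (and `severity_effect = 0` equates the severity distributions,
#' yielding a null cohort).
#'
#' @param n_patient,n_control group sizes.
#' @param seed RNG seed for the cohort.
#' @param duration_s recording length in seconds.
#' @param silence_frac control-group target silence (pause) time fraction.
#' @param silence_shift patient logit shift of the silence fraction,
#'   scaled by `timing_effect`.
#' @param severity_tilt per-participant logit tilt of the silence fraction
#'   per unit of (severity minus group mean).
#' @param speech_meanlog,speech_sdlog lognormal speech-segment durations (s).
#' @param pause_sdlog lognormal sdlog of pause durations (the location is set
#'   per participant from their target silence fraction).
#' @param min_segment_s minimum planted segment duration (default 0.25 s).
#' @param speech_rate nominal words per second of speech.
#' @param timing_effect,lexsem_effect,severity_effect effect multipliers.
#' @param pos_dir,depth_dir,switch_dir direction multipliers (+1/-1) for the
#'   three lexico-semantic group effects; re-randomized by the scrambled
#'   transfer mode.
#' @param mmse_intercept,mmse_slope,mmse_noise_sd severity-to-MMSE model.
#' @param synthesize_audio logical; also synthesize waveforms.
#' @param snr_db speech-to-noise ratio of synthesized audio (default 30).
#' @param language `"en"` or `"es"` (selects the toy lexicon variant).
#' @param transfer_mode `"aligned"` or `"scrambled_lexsem"` (used by
#'   [generate_language_pair()]).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_patient = 58L, n_control = 59L, seed = 1L,
                          duration_s = 30, silence_frac = 0.30,
                          silence_shift = 0.62, severity_tilt = 0.8,
                          speech_meanlog = log(1.5), speech_sdlog = 0.4,
                          pause_sdlog = 0.5, min_segment_s = 0.25,
                          speech_rate = 2.0,
                          timing_effect = 1, lexsem_effect = 1,
                          severity_effect = 1,
                          pos_dir = 1, depth_dir = 1, switch_dir = 1,
                          mmse_intercept = 27, mmse_slope = -6,
                          mmse_noise_sd = 2,
                          synthesize_audio = FALSE, snr_db = 30,
                          language = "en", transfer_mode = "aligned") {
  stopifnot(n_patient >= 2L, n_control >= 2L, duration_s > 0,
            silence_frac > 0, silence_frac < 1, mmse_noise_sd >= 0,
            snr_db > 0, transfer_mode %in% c("aligned", "scrambled_lexsem"))
  as.list(environment()) |> structure(class = "cohort_config")
}

# group parameter blocks derived from a config
group_params <- function(config, group) {
  pat <- group == "patient"
  eff <- config$lexsem_effect
  base_pos <- c(noun = 0.30, verb = 0.20, adjective = 0.08, adverb = 0.07,
                other = 0.35)
  shift <- c(noun = -0.08, verb = -0.02, adjective = -0.02, adverb = -0.01,
             other = 0.13) * eff * config$pos_dir
  pos <- if (pat) pmax(base_pos + shift, 0.01) else base_pos
  pos <- pos / sum(pos)
  list(
    sev_mean = if (pat) config$severity_effect else 0,
    silence = if (pat) {
      stats::plogis(stats::qlogis(config$silence_frac) +
                    config$silence_shift * config$timing_effect)
    } else config$silence_frac,
    rate_slow = if (pat) 0.15 * config$timing_effect else 0,
    pos = pos,
    depth_mean = if (pat) 6.5 - 2 * eff * config$depth_dir else 6.5,
    # cluster-jump rates are kept low so the variance contrast survives the
    # content-word / non-repeat filtering (which raises the effective rate)
    switch_prob = if (pat) {
      min(0.95, max(0.01, 0.05 + 0.25 * eff * config$switch_dir))
    } else 0.05
  )
}

syllable_count <- function(word) pmin(5L, pmax(1L, as.integer(round(nchar(gsub("_.*$", "", word)) / 3))))

# next word given the allowed candidate set, continuing a cluster random walk
walk_pick <- function(candidates, clusters, state, switch_prob) {
  cl <- clusters[candidates]
  if (!is.na(state$cluster) && stats::runif(1) >= switch_prob) {
    same <- candidates[cl == state$cluster]
    if (length(same)) candidates <- same
  } else if (length(unique(cl)) > 1L && !is.na(state$cluster)) {
    diff_cl <- candidates[cl != state$cluster]
    if (length(diff_cl)) candidates <- diff_cl
  }
  w <- candidates[sample.int(length(candidates), 1L)]
  state$cluster <- clusters[[w]]
  w
}

generate_segments <- function(config, silence_target) {
  mean_speech <- exp(config$speech_meanlog + config$speech_sdlog^2 / 2)
  mean_pause <- silence_target / (1 - silence_target) * mean_speech
  mu_p <- log(mean_pause) - config$pause_sdlog^2 / 2
  segs <- list(); total <- 0; speech <- TRUE
  while (total < config$duration_s) {
    d <- if (speech) {
      stats::rlnorm(1, config$speech_meanlog, config$speech_sdlog)
    } else {
      stats::rlnorm(1, mu_p, config$pause_sdlog)
    }
    d <- max(d, config$min_segment_s)
    segs[[length(segs) + 1L]] <- c(d, speech)
    total <- total + d
    speech <- !speech
  }
  m <- do.call(rbind, segs)
  ends <- pmin(cumsum(m[, 1]), config$duration_s)
  starts <- c(0, ends[-length(ends)])
  keep <- ends - starts > config$min_segment_s / 2
  if (!keep[length(keep)]) ends[max(which(keep))] <- config$duration_s
  data.frame(start_s = starts[keep], end_s = ends[keep],
             label = ifelse(m[keep, 2] == 1, "speech", "pause"),
             stringsAsFactors = FALSE)
}

generate_transcript <- function(config, seg, gp, lexicon, id) {
  clusters <- lexicon$clusters
  words <- lexicon$words
  depths_avail <- as.numeric(names(lexicon$nouns_by_depth))
  depth_w <- stats::dnorm(depths_avail, gp$depth_mean, 2)
  state <- new.env(); state$cluster <- NA_integer_
  rows <- list()
  for (i in which(seg$label == "speech")) {
    len <- seg$end_s[i] - seg$start_s[i]
    n_words <- max(1L, stats::rpois(1, config$speech_rate *
                                      exp(-gp$rate_slow) * len))
    cuts <- c(0, sort(stats::runif(n_words - 1L)), 1) * len
    for (k in seq_len(n_words)) {
      pos <- sample(names(gp$pos), 1L, prob = gp$pos)
      if (pos == "noun") {
        d <- sample(depths_avail, 1L, prob = depth_w)
        word <- walk_pick(lexicon$nouns_by_depth[[as.character(d)]],
                          clusters, state, gp$switch_prob)
        is_stop <- FALSE
      } else if (pos == "other") {
        is_stop <- stats::runif(1) < 0.75
        pool <- if (is_stop) words$stop else words$filler
        word <- walk_pick(pool, clusters, state, gp$switch_prob)
      } else {
        word <- walk_pick(words[[pos]], clusters, state, gp$switch_prob)
        is_stop <- FALSE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        token = word,
        onset_s = seg$start_s[i] + cuts[k],
        offset_s = seg$start_s[i] + cuts[k + 1L],
        pos = pos, syllables = syllable_count(word), is_stop = is_stop,
        stringsAsFactors = FALSE)
    }
  }
  aligned_transcript(do.call(rbind, rows), recording_id = id,
                     duration = config$duration_s)
}

# amplitude-modulated sawtooth speech bursts over low-level noise
synthesize_audio <- function(seg, snr_db, sr = 16000) {
  n <- as.integer(round(max(seg$end_s) * sr))
  amp <- 0.5
  noise_sd <- (amp / sqrt(3)) * 10^(-snr_db / 20)
  x <- stats::rnorm(n, sd = noise_sd)
  for (i in which(seg$label == "speech")) {
    a <- as.integer(round(seg$start_s[i] * sr)) + 1L
    b <- min(n, as.integer(round(seg$end_s[i] * sr)))
    if (b <= a) next
    t <- (0:(b - a)) / sr
    f0 <- stats::runif(1, 100, 150)
    saw <- 2 * ((t * f0) %% 1) - 1
    env <- 1 + 0.25 * sin(2 * pi * 3 * t)
    x[a:b] <- x[a:b] + amp * env * saw
  }
  audio_signal(pmax(-1, pmin(1, x)), sr)
}

#' Generate a synthetic cohort
#'
#' @param config a [cohort_config()].
#' @return object of class `speechmark_cohort`: `participants` (each with
#'   `id`, `group`, `severity`, `mmse`, `language`, a planted `segmentation`,
#'   an [aligned_transcript()], and optionally an [audio_signal()]),
#'   the `config`, the `lexicon` used, and a `ground_truth` data.frame with
#'   the planted per-participant quantities.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  lexicon <- bundled_toy_lexicon(config$language)
  groups <- c(rep("patient", config$n_patient),
              rep("control", config$n_control))
  participants <- vector("list", length(groups))
  gt <- vector("list", length(groups))
  with_local_seed(config$seed, {
    for (i in seq_along(groups)) {
      g <- groups[i]
      gp <- group_params(config, g)
      sev <- stats::rnorm(1, gp$sev_mean, 0.3)
      silence_target <- stats::plogis(
        stats::qlogis(gp$silence) + config$severity_tilt * (sev - gp$sev_mean))
      seg <- generate_segments(config, silence_target)
      id <- sprintf("%s_%s_%03d", config$language, substr(g, 1, 3), i)
      transcript <- generate_transcript(config, seg, gp, lexicon, id)
      mmse <- round(config$mmse_intercept + config$mmse_slope * sev +
                      stats::rnorm(1, 0, config$mmse_noise_sd))
      mmse <- max(0, min(30, mmse))
      audio <- if (config$synthesize_audio) {
        synthesize_audio(seg, config$snr_db)
      } else NULL
      participants[[i]] <- list(
        id = id, group = g, severity = sev, mmse = mmse,
        language = config$language,
        segmentation = segmentation_from_segments(seg),
        transcript = transcript, audio = audio)
      dur <- seg$end_s - seg$start_s
      gt[[i]] <- data.frame(
        id = id, group = g, severity = sev, mmse = mmse,
        silence_target = silence_target,
        silence_realized = sum(dur[seg$label == "pause"]) / sum(dur),
        n_pauses = sum(seg$label == "pause"),
        switch_prob = gp$switch_prob, depth_mean = gp$depth_mean,
        stringsAsFactors = FALSE)
    }
  })
  structure(list(participants = participants, config = config,
                 lexicon = lexicon, ground_truth = do.call(rbind, gt)),
            class = "speechmark_cohort")
}

#' @export
print.speechmark_cohort <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf("<speechmark_cohort> '%s': %d patients, %d controls (seed %d)\n",
              x$config$language, sum(gt$group == "patient"),
              sum(gt$group == "control"), x$config$seed))
  invisible(x)
}

#' Generate a source/target language pair
#'
#' The source cohort is generated in aligned mode. The target cohort keeps
#' the timing effect direction and magnitude; in `"scrambled_lexsem"` mode
#' its three lexico-semantic effect directions (POS shift, depth shift,
#' embedding-walk mixing) are independently re-randomized to +1 or -1 and its
#' embedding table is disjoint from the source's (the synthetic second
#' language). In `"aligned"` mode the target is a fresh draw from the same
#' effect structure.
#'
#' @param config a [cohort_config()] for the source; `transfer_mode` selects
#'   the target behaviour.
#' @param n_target_patient,n_target_control target group sizes (default
#'   47/47).
#' @return list with `source` and `target` cohorts.
#' @export
generate_language_pair <- function(config, n_target_patient = 47L,
                                   n_target_control = 47L) {
  stopifnot(inherits(config, "cohort_config"))
  source_cfg <- config
  source_cfg$transfer_mode <- "aligned"
  src <- generate_cohort(source_cfg)
  tgt_cfg <- config
  tgt_cfg$language <- "es"
  tgt_cfg$n_patient <- as.integer(n_target_patient)
  tgt_cfg$n_control <- as.integer(n_target_control)
  tgt_cfg$seed <- config$seed + 104729L
  if (config$transfer_mode == "scrambled_lexsem") {
    dirs <- with_local_seed(config$seed + 7L,
                            sample(c(-1, 1), 3L, replace = TRUE))
    tgt_cfg$pos_dir <- dirs[1]
    tgt_cfg$depth_dir <- dirs[2]
    tgt_cfg$switch_dir <- dirs[3]
  }
  list(source = src, target = generate_cohort(tgt_cfg))
}

#' Extract the full feature table of a cohort
#'
#' Timing features come from the planted segmentation (or, with
#' `from_audio = TRUE`, from running the energy VAD and the F0 tracker on the
#' synthesized waveforms); lexico-semantic features use the cohort's own
#' lexicon (hypernym graph + embedding table).
#'
#' @param cohort a `speechmark_cohort`.
#' @param from_audio recompute segmentations from audio via [detect_speech()]
#'   (requires `synthesize_audio = TRUE` at generation).
#' @return data.frame: `id`, `group`, `mmse`, `language`, then `timing__*`
#'   and `lexsem__*` feature columns.
#' @export
extract_cohort_features <- function(cohort, from_audio = FALSE) {
  stopifnot(inherits(cohort, "speechmark_cohort"))
  rows <- lapply(cohort$participants, function(p) {
    if (from_audio) {
      if (is.null(p$audio)) stop("cohort generated without audio")
      seg <- detect_speech(p$audio)
      vr <- voiced_rate(p$audio)$rate
    } else {
      seg <- p$segmentation
      vr <- NA_real_
    }
    feats <- c(timing_features(p$transcript, seg, vr),
               lexsem_features(p$transcript, cohort$lexicon$graph,
                               cohort$lexicon$embeddings))
    cbind(data.frame(id = p$id, group = p$group, mmse = p$mmse,
                     language = p$language, stringsAsFactors = FALSE),
          as.data.frame(as.list(feats)))
  })
  do.call(rbind, rows)
}
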