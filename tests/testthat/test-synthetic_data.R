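test_that("bundled toy lexicon satisfies its structural contracts", {
  lex <- bundled_toy_lexicon("en")
  g <- lex$graph
  expect_equal(unname(g$depths[c("animal", "dog", "bulldog")]), c(1, 2, 3))
  expect_true(all(is.finite(g$depths)))          # root reachable from all
  expect_lte(length(g$nodes), 200L)
  norms <- sqrt(rowSums(lex$embeddings$vectors^2))
  expect_true(all(norms > 0))
  # deterministic across calls
  lex2 <- bundled_toy_lexicon("en")
  expect_identical(lex$embeddings$vectors, lex2$embeddings$vectors)
  # the second language is disjoint in word forms and vectors
  es <- bundled_toy_lexicon("es")
  expect_length(intersect(setdiff(rownames(lex$embeddings$vectors), "entity"),
                          rownames(es$embeddings$vectors)), 0L)
})

test_that("cohorts are reproducible and structurally valid", {
  cfg <- cohort_config(n_patient = 4, n_control = 4, seed = 42,
                       duration_s = 15)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$participants[[3]]$transcript$tokens,
                   b$participants[[3]]$transcript$tokens)
  for (p in a$participants) {
    seg <- p$segmentation$segments
    expect_equal(sum(seg$end_s - seg$start_s), 15, tolerance = 1e-9)
    expect_true(all(p$mmse >= 0 & p$mmse <= 30))
    # every token lies inside a speech segment
    sp <- seg[seg$label == "speech", ]
    tok <- p$transcript$tokens
    inside <- vapply(seq_len(nrow(tok)), function(i)
      any(tok$onset_s[i] >= sp$start_s - 1e-9 &
            tok$offset_s[i] <= sp$end_s + 1e-9), logical(1))
    expect_true(all(inside))
  }
})

test_that("planted silence fractions are realized at the configured level", {
  cfg <- cohort_config(n_patient = 25, n_control = 25, seed = 7,
                       timing_effect = 0)  # both groups at silence_frac 0.3
  co <- generate_cohort(cfg)
  expect_lt(abs(mean(co$ground_truth$silence_realized) - 0.30), 0.03)
  # and the realized fraction tracks the per-participant target
  expect_lt(max(abs(co$ground_truth$silence_realized -
                      co$ground_truth$silence_target)), 0.12)
})

test_that("generated audio yields the planted segments back through the VAD", {
  co <- generate_cohort(cohort_config(n_patient = 2, n_control = 2, seed = 3,
                                      duration_s = 10,
                                      synthesize_audio = TRUE, snr_db = 25))
  for (p in co$participants) {
    est <- detect_speech(p$audio)
    truth <- p$segmentation$segments
    pr_true <- sum((truth$end_s - truth$start_s)[truth$label == "pause"]) / 10
    pr_est <- sum((est$segments$end_s -
                     est$segments$start_s)[est$segments$label == "pause"]) / 10
    expect_lt(abs(pr_true - pr_est), 0.05)
  }
})

test_that("language pairs preserve timing and scramble lexsem by direction", {
  cfg <- cohort_config(n_patient = 30, n_control = 30, seed = 5,
                       transfer_mode = "scrambled_lexsem")
  pair <- generate_language_pair(cfg, 25, 25)
  expect_equal(pair$source$config$language, "en")
  expect_equal(pair$target$config$language, "es")
  smd <- function(cohort) {
    gt <- cohort$ground_truth
    diff(rev(tapply(gt$silence_realized, gt$group, mean))) /
      sd(gt$silence_realized)
  }
  # timing contrast of the same sign and comparable size in both cohorts
  expect_lt(abs(smd(pair$source) - smd(pair$target)), 0.6)
  expect_gt(smd(pair$source) * smd(pair$target), 0)

  # scrambled directions come from the seed and take values in {-1, 1}
  dirs <- c(pair$target$config$pos_dir, pair$target$config$depth_dir,
            pair$target$config$switch_dir)
  expect_true(all(dirs %in% c(-1, 1)))
  # aligned mode leaves the directions untouched
  aligned <- generate_language_pair(cohort_config(n_patient = 4,
                                                  n_control = 4, seed = 5), 3, 3)
  expect_equal(c(aligned$target$config$pos_dir,
                 aligned$target$config$depth_dir,
                 aligned$target$config$switch_dir), c(1, 1, 1))
})

test_that("lexsem contrast signs agree at chance rate under scrambling", {
  signs <- sapply(1:8, function(s) {
    pair <- generate_language_pair(
      cohort_config(n_patient = 15, n_control = 15, seed = 300 + s,
                    transfer_mode = "scrambled_lexsem"), 15, 15)
    con <- function(cohort, col) {
      ft <- extract_cohort_features(cohort)
      m <- tapply(ft[[col]], ft$group, mean, na.rm = TRUE)
      m["patient"] - m["control"]
    }
    con(pair$source, "lexsem__granularity__mean") *
      con(pair$target, "lexsem__granularity__mean") > 0
  })
  # depth_dir is resampled per seed: agreement must not be systematic
  expect_gt(sum(signs), 0)
  expect_lt(sum(signs), 8)
})

test_that("the feature table carries both modalities and group metadata", {
  co <- generate_cohort(cohort_config(n_patient = 3, n_control = 3, seed = 2,
                                      duration_s = 15))
  ft <- extract_cohort_features(co)
  expect_equal(nrow(ft), 6L)
  expect_true(any(grepl("^timing__", names(ft))))
  expect_true(any(grepl("^lexsem__", names(ft))))
  expect_setequal(unique(ft$group), c("patient", "control"))
  # planted pause ratio is reported exactly when using planted segments
  expect_equal(ft$timing__pause_duration_ratio,
               co$ground_truth$silence_realized, tolerance = 1e-9)
})
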