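---
title: "Methods: interpretable speech and language markers of dementia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interpretable speech and language markers of dementia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechmark)
```

## The problem

In Alzheimer's dementia, word retrieval becomes effortful and conceptual
precision degrades. Both show up in connected speech elicited by a picture
description: patients pause longer and more often (retrieval effort), prefer
more general nouns (lower *semantic granularity*), and jump between more
distant concepts from word to word (higher *semantic variability*).
`speechmark` implements a pipeline that extracts these interpretable markers
from a recording and its time-aligned transcript, classifies patients versus
controls with a deliberately transparent model, and evaluates how well a
model trained in one language transfers, zero-shot, to another. Because the
clinical corpora this methodology was developed on are access-restricted,
the package ships a synthetic cohort generator that plants all of these
effects with known ground truth; every empirical claim in the test suite is
a claim about that synthetic world.

## Voice activity detection

Speech/pause segmentation uses short-time log energy: 25 ms windows, 10 ms
hop, `log(mean(x^2))` floored at `1e-10` (so digital silence maps to a
finite value rather than $-\infty$). The trace is mean-subtracted (DC
removal) and convolved with a normalized Gaussian window (default width
10 ms, $\sigma$ = half the width, truncated at $3\sigma$, reflected edges).
Mean subtraction makes the whole chain invariant to global amplitude
scaling, since a gain change only shifts log energy by a constant.

The speech/silence threshold is "heuristic but systematic": a two-means
iteration on the smoothed trace, initialized at the 10th and 90th
percentiles, with the threshold at the midpoint of the converged cluster
means. It is estimated **per recording**, which makes the detector robust to
recording-level gain differences but assumes each recording contains both
speech and silence; a zero-variance trace raises an error rather than
guessing. Frame runs become segments, with boundaries midway between frame
centres; segments shorter than 50 ms (5 hops) are merged into their
neighbours, shortest first. Boundary placement is quantized by the analysis
window, so planted boundaries are recovered to about half a window
(±12.5 ms) on clean synthetic signals — comfortably inside the ±25 ms
acceptance band.

Voiced rate (voiced segments per second) comes from an independent
autocorrelation F0 tracker: 32 ms frames, search range 60–400 Hz, a frame is
voiced when its normalized autocorrelation peak is at least 0.5. The
original pipeline used an external toolkit without published parameters;
these values are standard defaults and are exposed as arguments.

## Timing features

Whole-recording features: `pause_duration_ratio` and
`speech_segment_duration_ratio` are time fractions (they sum to 1 by
construction); `pause_ratio` is the *count* fraction of pause segments. The
source material names these features without defining them; the
time-fraction/count-fraction split is the only reading that makes all the
names distinct, and it is fixed here. Pause and speech-segment durations
each get six summary statistics — mean, SD, adjusted Fisher–Pearson
skewness, adjusted excess kurtosis, min, max — with skewness and kurtosis
defined as 0 on zero-variance or too-short series.

Word-level features are computed per token category: all words, stop words,
content words, other words, the stop+content union, and a per-syllable
proxy (each token expanded into `n_syllables` equal-duration
pseudo-syllables, since sub-word alignment is not available).
`normalized_word_duration` divides by the syllable count (a rough
articulation-rate correction); `normalized_word_count` divides by total
speech time, i.e. words per second of speech. Both normalization bases were
unspecified upstream; these are the standard speech-rate conventions.
Syllable counts and stop-word flags are *inputs*, read from the transcript
file: both are language-dependent and produced by upstream tooling, so the
package deliberately does not hard-code either.

Empty categories yield `NA` markers, never zeros — a zero word count is a
statement about speech, a missing category is not.

## Lexico-semantic features

Word-class ratios are computed twice, relative to all words and to content
words only (content = noun, verb, adjective, adverb). Granularity of a word
is the minimum number of hypernym edges from any of its senses to the root
`entity`, found by breadth-first search; the canonical ordering is
animal < dog < bulldog. Out-of-vocabulary words are excluded and logged,
never zero-imputed — a zero would masquerade as maximal generality. Bin
boundaries for the low/intermediate/high proportions default to depth ≤ 4 /
5–7 / ≥ 8 (configurable; the source mentions bins only illustratively), and
proportions are taken over the *total* word count, so the three proportions
sum to the in-vocabulary fraction. Whether granularity should cover all
words or content words only is unspecified upstream; the default is all
in-vocabulary words, with `words = "content"` available.

Semantic variability filters the token sequence (content words;
non-repeated adjacent words; non-repeated adjacent content words — "
non-repeated" collapses runs of identical word forms after OOV removal),
computes cosine distances between adjacent embedding vectors, and returns
the sample variance of that series. Cosine was chosen because it is
scale-free (verified by a rescaling invariance test); Euclidean is available
behind `metric=`. Fewer than two distances yields an `NA` marker.

The embedding table and hypernym graph are injected dependencies. The
bundled toy lexicon is **synthetic**: a ~110-node taxonomy and a clustered
12-dimensional embedding table, deterministic across calls. It emulates
depth structure and cluster geometry, not distributional semantics; a green
test establishes algorithmic correctness, not linguistic validity. Real
WordNet exports (edge-list TSV) and word2vec-format text tables load through
the same interfaces.

## The tree-guided sparse MLP

A CART ensemble (bootstrap resamples, $\sqrt{p}$ feature subsampling per
node, Gini or variance criterion, depth-limited) is fitted first; ensemble
construction is not described in the source beyond its grid
(trees ∈ {10, 20, 40, 60, 80, 100} × depth ∈ {4, 6, 8, 10}), so
random-forest-style diversification was chosen to give the hidden units
distinct feature sets. Each tree then becomes one hidden unit of a partially
connected MLP, wired only to the features that tree split on. "Multilayer"
is read as one sparse hidden layer plus a dense output — the minimal
architecture consistent with "each neuron specializes in processing a
specific tree" — with ReLU hidden activation and sigmoid (classification) or
linear (regression) output, none of which were specified upstream.

Training is full-batch Adam (learning rate 1e-3, max 500 epochs), ridge
penalty 1e-3 on weights, class weights $w_c = n/(K n_c)$ on the
cross-entropy, early stopping with patience 10 on a validation fold (20% of
the training participants, stratified), best-epoch weights restored.
Masked weights are re-zeroed after every update, so structural zeros are
exact at all times, and feature importance is simply the per-feature count
of connected hidden units. Regression targets are standardized with
training-set parameters inside the pipeline (and predictions unscaled), so
the output layer trains on an O(1) scale; without this the MMSE scale
(0–30) would stall a small-step optimizer.

## Evaluation protocols

Splits are stratified by group and speaker-independent. Features are
median-imputed and z-scored with training-fold parameters only; constant
training features are dropped with a warning. Within-language evaluation
repeats the stratified 80/20 split (default 50 repetitions, per-repetition
retraining) and reports the mean held-out AUC along with the per-repetition
values; the source material's "bootstrapping strategy with an 80/20 split"
does not state its resampling unit, and repeated stratified resampling is
the reading that keeps speaker independence exact. Between-language
evaluation is strictly zero-shot: the model, its imputation medians, its
z-scoring parameters, and any grid selection are fitted on the source
cohort alone, then the entire target cohort is scored once. The test suite
verifies this at the strongest available level — the trained model is
bit-identical no matter which target is supplied.

AUC is trapezoidal over the tie-aware ROC (equal to the Mann–Whitney
statistic); paired AUCs are compared with the DeLong placement-value test,
two-sided, with a zero-variance comparison (e.g. a model against itself)
reported as p = 1 with a degenerate flag rather than NaN. MMSE prediction is
scored by Spearman's ρ (average ranks) and RMSE in MMSE points.

## The synthetic world

Defaults mirror the emulated study design: 58 patients / 59 controls in the
source cohort, 47/47 in the target, 16 kHz audio. Latent severity is
N(0, 0.3) in controls and N(1, 0.3) in patients. The silence fraction is
0.30 in controls, shifted by +0.62 logits in patients (≈ 0.45), with a
+0.8 logit/severity-unit within-group tilt so timing carries severity
information; pause durations are lognormal with the location set from the
participant's target fraction, speech segments lognormal(log 1.5, 0.4),
everything clamped at 250 ms (shorter planted segments would be
unrecoverable by design under the 50 ms merge rule). MMSE =
27 − 6·severity + N(0, 2), clipped to [0, 30] — patient/control means near
21 and 27, echoing the clinical order of magnitude without copying any
cohort's values. Patients get fewer nouns and more function/filler words,
shallower noun depths (6.5 → 4.5 mean), and a higher embedding cluster-jump
rate (0.05 → 0.30); jump rates are kept low because the content-word and
non-repeat filters thin the token series and raise the effective jump rate
of what remains — a rate near 0.5 after thinning would *reduce* the
distance-series variance and invert the planted effect.

Synthesized audio uses amplitude-modulated sawtooth carriers (100–150 Hz)
for speech — periodic, hence genuinely voiced for the F0 tracker — over
low-level Gaussian noise at a configurable SNR (default 30 dB, acceptance
tests use 20 dB). Scrambled transfer mode re-randomizes the *directions* of
the three lexico-semantic effects (±1 each, seeded) and switches to a
disjoint synthetic "second language" lexicon, while the timing effect is
untouched: a source-trained timing model transfers by construction, a
lexico-semantic one averages to chance across seeds. The generator does not
emulate examiner speech, disfluency structure, channel noise, or any real
distributional semantics — green tests certify the pipeline's mechanics and
its leakage discipline, not clinical performance.

## Numerical choices and degenerate inputs

* Energy floor 1e-10 before the log; silent recordings segment as one pause.
* Zero-variance energy traces, single-class labels, empty validation sets,
  and constant prediction vectors raise errors or flagged `NA`s — never
  silent zeros.
* Two-means initialization falls back from percentiles to the range if the
  10th and 90th percentiles coincide.
* Grid-search ties break toward fewer trees, then smaller depth (the
  simpler model).
* All randomness flows through explicit integer seeds; cohorts, splits,
  bootstrap resamples and weight initializations are reproducible
  bit-for-bit.

## A worked example

```{r example, eval = FALSE}
cohort <- generate_cohort(cohort_config(n_patient = 30, n_control = 30,
                                        seed = 1, duration_s = 20))
features <- extract_cohort_features(cohort)
report <- run_protocol(features, modality = "fusion",
                       config = list(n_boot = 3, seed = 1, spec = c(20, 4)))
report
#> <evaluation_report> within-language, fusion, classification
#>   mean held-out AUC over 3 repetitions: 0.917
```

## Known limitations

* The resampler is linear-interpolation; adequate for energy/F0 features,
  not for spectral analysis.
* The F0 tracker is a plain autocorrelation peak-picker; it is exercised on
  clean synthetic carriers only.
* One sparse hidden layer; deeper tree-guided variants are a flagged
  extension point.
* The toy lexicon is a stand-in. Nothing in the test suite validates
  behaviour on real WordNet or fastText assets beyond format compatibility.
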