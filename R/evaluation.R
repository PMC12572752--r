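#' @title Evaluation harness
#' @description
#' Speaker-independent stratified splits, leakage-free z-scoring, early
#' fusion of feature modalities, ROC/AUC, paired DeLong AUC comparisons, and
#' Spearman/RMSE regression metrics. The protocol driver supports a
#' within-language setting (repeated stratified 80/20 resampling with
#' per-repetition retraining) and a zero-shot between-language setting (train
#' and select on the source cohort only, evaluate once on the full target
#' cohort with source-fitted normalization).
#' @name evaluation
NULL

#' Stratified speaker-independent split
#'
#' @param manifest data.frame with columns `id` and `group`.
#' @param fraction training fraction (default 0.8).
#' @param seed RNG seed.
#' @return object of class `split_plan`: `train` and `test` id vectors,
#'   disjoint, exhaustive, with per-group train proportions within one
#'   participant of `fraction`.
#' @export
make_split <- function(manifest, fraction = 0.8, seed = 1L) {
  stopifnot(all(c("id", "group") %in% names(manifest)),
            fraction > 0, fraction < 1)
  counts <- table(manifest$group)
  if (any(counts < 2L)) stop("group too small to stratify: ",
                             names(counts)[which.min(counts)])
  train <- character(0)
  with_local_seed(seed, {
    for (g in sort(unique(manifest$group))) {
      ids <- manifest$id[manifest$group == g]
      n_tr <- max(1L, min(length(ids) - 1L, round(fraction * length(ids))))
      train <- c(train, sample(ids, n_tr))
    }
  })
  structure(list(train = sort(train),
                 test = sort(setdiff(manifest$id, train)),
                 fraction = fraction, seed = seed),
            class = "split_plan")
}

#' Impute missing feature values with train-column medians
#'
#' Columns that are entirely missing in the training data are dropped from
#' both sets.
#'
#' @param train,test numeric matrices (same columns).
#' @return list `train`, `test`, `medians`, `dropped`.
#' @export
impute_median <- function(train, test = NULL) {
  med <- apply(train, 2L, stats::median, na.rm = TRUE)
  dropped <- colnames(train)[!is.finite(med)]
  keep <- is.finite(med)
  train <- train[, keep, drop = FALSE]
  med <- med[keep]
  fill <- function(M) {
    for (j in seq_len(ncol(M))) M[is.na(M[, j]), j] <- med[j]
    M
  }
  list(train = fill(train),
       test = if (is.null(test)) NULL else fill(test[, keep, drop = FALSE]),
       medians = med, dropped = dropped)
}

#' Z-score features with training parameters only
#'
#' Both sets are transformed with the train mean and standard deviation;
#' the test set never contributes to the parameters. Zero-variance training
#' columns are dropped from both sets with a warning.
#'
#' @param train,test numeric matrices with identical columns (`test` may be
#'   `NULL`).
#' @return list `train`, `test`, `center`, `scale`, `dropped`.
#' @export
zscore_fit_transform <- function(train, test = NULL) {
  ctr <- colMeans(train)
  scl <- apply(train, 2L, stats::sd)
  dropped <- colnames(train)[!is.finite(scl) | scl == 0]
  if (length(dropped)) {
    warning("dropping constant feature(s): ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ...")
  }
  keep <- is.finite(scl) & scl > 0
  tf <- function(M) {
    M <- M[, keep, drop = FALSE]
    sweep(sweep(M, 2L, ctr[keep]), 2L, scl[keep], `/`)
  }
  list(train = tf(train), test = if (is.null(test)) NULL else tf(test),
       center = ctr[keep], scale = scl[keep], dropped = dropped)
}

#' Early fusion of two feature tables
#'
#' Column-wise concatenation of modality tables, row-aligned by participant
#' id. Column provenance is preserved by the `timing__` / `lexsem__`
#' prefixes.
#'
#' @param timing,lexsem data.frames with an `id` column and feature columns.
#' @return data.frame with `id` and both feature sets.
#' @export
early_fusion <- function(timing, lexsem) {
  stopifnot("id" %in% names(timing), "id" %in% names(lexsem))
  if (!setequal(timing$id, lexsem$id)) stop("participant id sets differ")
  lex <- lexsem[match(timing$id, lexsem$id), , drop = FALSE]
  cbind(timing, lex[, setdiff(names(lex), "id"), drop = FALSE])
}

#' ROC curve and AUC
#'
#' Thresholds sweep all distinct scores; tied scores move the curve
#' diagonally in a single step. The AUC is the trapezoidal area, which for
#' this construction equals the Mann-Whitney probability of correct ranking
#' with ties counted 1/2.
#'
#' @param scores numeric scores, larger = more patient-like.
#' @param labels 0/1 labels (1 = positive class).
#' @return list with `auc` and `roc` (data.frame `fpr`, `tpr` from (0,0) to
#'   (1,1)).
#' @export
auc_roc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp <- cumsum(l); fp <- cumsum(1L - l)
  last <- c(which(diff(grp) != 0), length(s))
  roc <- data.frame(fpr = c(0, fp[last] / n_neg),
                    tpr = c(0, tp[last] / n_pos))
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  list(auc = auc, roc = roc)
}

# Placement values: for each positive, the fraction of negatives it
# outranks (ties 1/2); and symmetrically for negatives.
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  v_pos <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)),
                  numeric(1))
  v_neg <- vapply(neg, function(x) mean((pos > x) + 0.5 * (pos == x)),
                  numeric(1))
  list(v_pos = v_pos, v_neg = v_neg, auc = mean(v_pos))
}

#' Paired DeLong test for two correlated AUCs
#'
#' Both score vectors must be computed on the same samples. The variance of
#' the AUC difference is estimated from the empirical covariance of the
#' placement values; the p value is two-sided normal. A zero estimated
#' variance (e.g. comparing a model with itself) is reported as `p = 1` with
#' `degenerate = TRUE`.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels shared 0/1 labels.
#' @return list `delta_auc` (A minus B), `auc_a`, `auc_b`, `z`, `p`,
#'   `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  labels <- as.integer(labels)
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- length(pa$v_pos); n <- length(pa$v_neg)
  s10 <- stats::cov(cbind(pa$v_pos, pb$v_pos))
  s01 <- stats::cov(cbind(pa$v_neg, pb$v_neg))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- pa$auc - pb$auc
  if (!is.finite(var_delta) || var_delta <= 0) {
    return(list(delta_auc = delta, auc_a = pa$auc, auc_b = pb$auc,
                z = NA_real_, p = 1, degenerate = TRUE))
  }
  z <- delta / sqrt(var_delta)
  list(delta_auc = delta, auc_a = pa$auc, auc_b = pb$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' Spearman correlation and RMSE for MMSE prediction
#'
#' Spearman's rho uses average ranks for ties; RMSE is in MMSE points. A
#' constant vector makes rho undefined (`NA` with `degenerate = TRUE`).
#'
#' @param predicted,actual numeric vectors (>= 3 pairs).
#' @return list `spearman_rho`, `rmse`, `degenerate`.
#' @export
regression_metrics <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual), length(actual) >= 3L)
  rmse <- sqrt(mean((predicted - actual)^2))
  if (stats::sd(predicted) == 0 || stats::sd(actual) == 0) {
    return(list(spearman_rho = NA_real_, rmse = rmse, degenerate = TRUE))
  }
  rho <- stats::cor(rank(predicted), rank(actual))
  list(spearman_rho = rho, rmse = rmse, degenerate = FALSE)
}
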