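#' @title Within- and between-language protocols
#' @description
#' The protocol driver reproduces the experimental harness: features are
#' median-imputed and z-scored with training parameters only, a tree
#' ensemble guides the sparse MLP connectivity, early stopping uses an inner
#' validation fold carved out of the training participants, and evaluation is
#' by repeated stratified 80/20 resampling (within-language) or one-shot
#' scoring of an untouched target cohort (between-language, zero-shot).
#' @name protocol
NULL

feature_columns <- function(features, modality = c("fusion", "timing", "lexsem")) {
  modality <- match.arg(modality)
  cols <- names(features)
  pick <- switch(modality,
    timing = grepl("^timing__", cols),
    lexsem = grepl("^lexsem__", cols),
    fusion = grepl("^(timing|lexsem)__", cols))
  if (!any(pick)) stop("no feature columns for modality '", modality, "'")
  cols[pick]
}

feature_matrix <- function(features, modality) {
  as.matrix(features[, feature_columns(features, modality), drop = FALSE])
}

#' Fit the full modelling pipeline on a training table
#'
#' Imputation (train medians), z-scoring (train parameters), an inner
#' stratified validation split for early stopping, tree-ensemble fitting,
#' and sparse-MLP training; with `spec = NULL` a grid search over
#' `trees_grid x depth_grid` is run on the inner validation fold.
#'
#' @param X_train numeric feature matrix (may contain `NA`).
#' @param y 0/1 labels (classification) or numeric targets (regression).
#' @param task `"classification"` or `"regression"`.
#' @param spec `c(n_trees, depth)` for a fixed architecture, or `NULL` for
#'   grid search.
#' @param seed RNG seed (inner split, trees, weight init).
#' @param val_fraction inner validation fraction (default 0.2).
#' @param mlp_config list passed to [sparse_mlp()].
#' @param trees_grid,depth_grid grids used when `spec` is `NULL`.
#' @return object of class `speech_model` wrapping the preprocessing
#'   parameters and the trained [sparse_mlp()].
#' @export
fit_speech_model <- function(X_train, y, task = "classification",
                             spec = c(40, 6), seed = 1L, val_fraction = 0.2,
                             mlp_config = list(),
                             trees_grid = c(10, 20, 40, 60, 80, 100),
                             depth_grid = c(4, 6, 8, 10)) {
  stopifnot(is.matrix(X_train), nrow(X_train) == length(y))
  imp <- impute_median(X_train)
  zs <- zscore_fit_transform(imp$train)
  X <- zs$train
  n <- nrow(X)
  # regression targets are standardized with training parameters so the
  # output layer trains on an O(1) scale; predictions are unscaled on exit
  y_center <- 0; y_scale <- 1
  if (task == "regression") {
    y_center <- mean(y)
    y_scale <- stats::sd(y)
    if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
    y <- (y - y_center) / y_scale
  }
  strat <- if (task == "classification") y else rep(0L, n)
  plan <- make_split(data.frame(id = as.character(seq_len(n)), group = strat),
                     fraction = 1 - val_fraction, seed = seed)
  fit_idx <- as.integer(plan$train); val_idx <- as.integer(plan$test)
  cfg <- utils::modifyList(mlp_config, list(seed = seed))
  if (is.null(spec)) {
    gs <- grid_search(X[fit_idx, , drop = FALSE], y[fit_idx],
                      X[val_idx, , drop = FALSE], y[val_idx],
                      trees_grid, depth_grid, task, cfg, seed)
    ensemble <- gs$spec; model <- gs$model; grid_results <- gs$results
  } else {
    ensemble <- fit_tree_ensemble(X[fit_idx, , drop = FALSE], y[fit_idx],
                                  tree_ensemble_spec(spec[1], spec[2], seed),
                                  task)
    model <- sparse_mlp(build_mask(ensemble, ncol(X)), task, cfg)
    model <- train_sparse_mlp(model, X[fit_idx, , drop = FALSE], y[fit_idx],
                              X[val_idx, , drop = FALSE], y[val_idx])
    grid_results <- NULL
  }
  structure(list(model = model, ensemble = ensemble,
                 medians = imp$medians, center = zs$center, scale = zs$scale,
                 y_center = y_center, y_scale = y_scale,
                 feature_names = names(zs$center), task = task, seed = seed,
                 grid_results = grid_results),
            class = "speech_model")
}

#' Predict from a fitted pipeline
#'
#' @param object a `speech_model`.
#' @param newdata numeric feature matrix with (at least) the training
#'   columns; missing values are imputed with the *training* medians and
#'   features are z-scored with the *training* parameters.
#' @param ... unused.
#' @return scores (classification) or predictions (regression).
#' @export
predict.speech_model <- function(object, newdata, ...) {
  cols <- names(object$medians)
  missing_cols <- setdiff(cols, colnames(newdata))
  if (length(missing_cols)) stop("newdata lacks feature(s): ", missing_cols[1])
  M <- newdata[, cols, drop = FALSE]
  for (j in seq_len(ncol(M))) M[is.na(M[, j]), j] <- object$medians[j]
  M <- M[, object$feature_names, drop = FALSE]
  M <- sweep(sweep(M, 2L, object$center), 2L, object$scale, `/`)
  out <- predict(object$model, M)
  if (object$task == "regression") out * object$y_scale + object$y_center
  else out
}

as_feature_table <- function(x, from_audio = FALSE) {
  if (inherits(x, "speechmark_cohort")) extract_cohort_features(x, from_audio)
  else x
}

protocol_labels <- function(features, task) {
  if (task == "classification") as.integer(features$group == "patient")
  else as.numeric(features$mmse)
}

#' Run the within- or between-language evaluation protocol
#'
#' Within-language (no `target`): repeated stratified 80/20 participant
#' splits with per-repetition retraining; reports the per-repetition and
#' mean test AUC (classification) or Spearman rho / RMSE (regression), plus
#' the ROC of the first repetition. Between-language (`target` given): the
#' model is trained and early-stopped entirely on the source cohort's 80%
#' training fold, the source 20% fold is scored for reference, and the whole
#' target cohort is scored zero-shot with source-fitted imputation and
#' normalization parameters — no target row influences any fitted quantity.
#'
#' @param source feature table (from [extract_cohort_features()]) or a
#'   `speechmark_cohort`.
#' @param target optional target feature table or cohort (between mode).
#' @param modality `"timing"`, `"lexsem"` or `"fusion"`.
#' @param task `"classification"` or `"regression"` (regression predicts
#'   MMSE and is evaluated on participants with an MMSE score).
#' @param config list: `n_boot` (within-mode repetitions, default 50),
#'   `fraction` (0.8), `seed` (1), `spec` (`c(n_trees, depth)`, default
#'   `c(40, 6)`; `NULL` triggers grid search), `mlp` (config list for
#'   [sparse_mlp()]), `trees_grid`, `depth_grid`.
#' @return object of class `evaluation_report`.
#' @export
run_protocol <- function(source, target = NULL,
                         modality = c("fusion", "timing", "lexsem"),
                         task = c("classification", "regression"),
                         config = list()) {
  modality <- match.arg(modality)
  task <- match.arg(task)
  cfg <- utils::modifyList(
    list(n_boot = 50L, fraction = 0.8, seed = 1L, spec = c(40, 6),
         mlp = list(), trees_grid = c(10, 20, 40, 60, 80, 100),
         depth_grid = c(4, 6, 8, 10)),
    config)
  src <- as_feature_table(source)
  if (task == "regression") src <- src[is.finite(src$mmse), , drop = FALSE]
  X <- feature_matrix(src, modality)
  y <- protocol_labels(src, task)

  if (is.null(target)) {
    boot <- vector("list", cfg$n_boot)
    roc1 <- NULL
    scores1 <- NULL
    for (r in seq_len(cfg$n_boot)) {
      seed_r <- cfg$seed + r - 1L
      plan <- make_split(data.frame(id = src$id,
                                    group = if (task == "classification")
                                      src$group else "all"),
                         fraction = cfg$fraction, seed = seed_r)
      tr <- src$id %in% plan$train
      fit <- fit_speech_model(X[tr, , drop = FALSE], y[tr], task,
                              spec = cfg$spec, seed = seed_r,
                              mlp_config = cfg$mlp,
                              trees_grid = cfg$trees_grid,
                              depth_grid = cfg$depth_grid)
      sc <- predict(fit, X[!tr, , drop = FALSE])
      if (task == "classification") {
        ar <- auc_roc(sc, y[!tr])
        boot[[r]] <- data.frame(rep = r, auc = ar$auc)
        if (r == 1L) { roc1 <- ar$roc; scores1 <- data.frame(id = src$id[!tr], score = sc, label = y[!tr]) }
      } else {
        rm_ <- regression_metrics(sc, y[!tr])
        boot[[r]] <- data.frame(rep = r, spearman_rho = rm_$spearman_rho,
                                rmse = rm_$rmse)
      }
    }
    boot <- do.call(rbind, boot)
    rep_ <- list(setting = "within", modality = modality, task = task,
                 boot = boot, roc = roc1, holdout_scores = scores1,
                 config = cfg)
    if (task == "classification") {
      rep_$auc <- mean(boot$auc)
      rep_$auc_first <- boot$auc[1]
    } else {
      rep_$spearman_rho <- mean(boot$spearman_rho, na.rm = TRUE)
      rep_$rmse <- mean(boot$rmse)
    }
    return(structure(rep_, class = "evaluation_report"))
  }

  # between-language, zero-shot: everything fitted before the target is read
  plan <- make_split(data.frame(id = src$id,
                                group = if (task == "classification")
                                  src$group else "all"),
                     fraction = cfg$fraction, seed = cfg$seed)
  tr <- src$id %in% plan$train
  fit <- fit_speech_model(X[tr, , drop = FALSE], y[tr], task,
                          spec = cfg$spec, seed = cfg$seed,
                          mlp_config = cfg$mlp, trees_grid = cfg$trees_grid,
                          depth_grid = cfg$depth_grid)
  source_holdout <- predict(fit, X[!tr, , drop = FALSE])

  tgt <- as_feature_table(target)
  if (task == "regression") tgt <- tgt[is.finite(tgt$mmse), , drop = FALSE]
  Xt <- feature_matrix(tgt, modality)
  yt <- protocol_labels(tgt, task)
  sc <- predict(fit, Xt)
  rep_ <- list(setting = "between", modality = modality, task = task,
               model = fit, config = cfg,
               target_scores = data.frame(id = tgt$id, score = sc, label = yt))
  if (task == "classification") {
    ar <- auc_roc(sc, yt)
    rep_$auc <- ar$auc
    rep_$roc <- ar$roc
    rep_$source_holdout_auc <- auc_roc(source_holdout, y[!tr])$auc
  } else {
    rm_ <- regression_metrics(sc, yt)
    rep_$spearman_rho <- rm_$spearman_rho
    rep_$rmse <- rm_$rmse
  }
  structure(rep_, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s-language, %s, %s\n",
              x$setting, x$modality, x$task))
  if (x$task == "classification") {
    if (x$setting == "within") {
      cat(sprintf("  mean held-out AUC over %d repetitions: %.3f\n",
                  nrow(x$boot), x$auc))
    } else {
      cat(sprintf("  zero-shot target AUC: %.3f (source hold-out AUC %.3f)\n",
                  x$auc, x$source_holdout_auc))
    }
  } else {
    cat(sprintf("  Spearman rho %.3f, RMSE %.2f MMSE points\n",
                x$spearman_rho, x$rmse))
  }
  invisible(x)
}
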