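#' @title Decision-tree-guided sparse multilayer perceptron
#' @description
#' The classifier/regressor couples a small CART ensemble with a partially
#' connected one-hidden-layer perceptron. Each hidden unit corresponds to one
#' tree and receives input *only* from the features that tree actually split
#' on; all other input weights are structurally zero before, during and after
#' training. This keeps the parameter count far below a dense MLP and makes
#' feature importance directly readable: the importance of a feature is the
#' number of hidden units wired to it.
#'
#' Training uses full-batch Adam on a class-weighted cross-entropy
#' (classification) or squared-error (regression) loss with a ridge penalty
#' on the weights, and early stopping on a validation set with a patience of
#' 10 epochs (best-epoch weights restored).
#' @name tree_sparse_mlp
NULL

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Tree-ensemble specification
#'
#' @param n_trees number of trees (the study grid uses
#'   10, 20, 40, 60, 80, 100).
#' @param depth maximum tree depth in splits (grid: 4, 6, 8, 10).
#' @param seed RNG seed for bootstrap resampling and feature subsampling.
#' @return object of class `tree_ensemble_spec`.
#' @export
tree_ensemble_spec <- function(n_trees, depth, seed = 1L) {
  stopifnot(n_trees >= 1L, depth >= 1L)
  structure(list(n_trees = as.integer(n_trees), depth = as.integer(depth),
                 seed = as.integer(seed), trees = NULL, used_features = NULL),
            class = "tree_ensemble_spec")
}

# Best binary split of (X, y) rows `rows` among candidate features `feats`.
# Classification: Gini impurity decrease; regression: variance decrease.
best_split <- function(X, y, rows, feats, task) {
  n <- length(rows)
  best <- list(gain = 0, feature = NA_integer_, threshold = NA_real_)
  yr <- y[rows]
  for (f in feats) {
    xv <- X[rows, f]
    ord <- order(xv)
    xs <- xv[ord]; ys <- yr[ord]
    distinct <- which(diff(xs) > 0)
    if (!length(distinct)) next
    nl <- distinct                       # left counts at each cut
    if (task == "classification") {
      csum <- cumsum(ys)[distinct]
      pl <- csum / nl
      pr <- (sum(ys) - csum) / (n - nl)
      imp <- (nl * 2 * pl * (1 - pl) + (n - nl) * 2 * pr * (1 - pr)) / n
      p0 <- mean(ys)
      gain <- 2 * p0 * (1 - p0) - imp
    } else {
      cs <- cumsum(ys)[distinct]
      cs2 <- cumsum(ys^2)[distinct]
      tot <- sum(ys); tot2 <- sum(ys^2)
      varl <- cs2 - cs^2 / nl
      varr <- (tot2 - cs2) - (tot - cs)^2 / (n - nl)
      gain <- (tot2 - tot^2 / n) - (varl + varr)   # SSE decrease (>= 0)
    }
    j <- which.max(gain)
    if (gain[j] > best$gain + 1e-12) {
      best <- list(gain = gain[j], feature = f,
                   threshold = (xs[distinct[j]] + xs[distinct[j] + 1L]) / 2)
    }
  }
  best
}

# Depth-limited CART on the given rows; features are subsampled per node
# (random-forest style). Returns a nested node list and records used features
# in `env$used`.
grow_tree <- function(X, y, rows, depth_left, mtry, task, min_node, env) {
  yr <- y[rows]
  pred <- mean(yr)
  if (depth_left == 0L || length(rows) < 2L * min_node ||
      stats::var(yr) == 0) {
    return(list(leaf = TRUE, pred = pred))
  }
  feats <- sample.int(ncol(X), mtry)
  sp <- best_split(X, y, rows, feats, task)
  if (is.na(sp$feature)) return(list(leaf = TRUE, pred = pred))
  env$used <- c(env$used, sp$feature)
  left <- rows[X[rows, sp$feature] <= sp$threshold]
  right <- setdiff(rows, left)
  if (!length(left) || !length(right)) return(list(leaf = TRUE, pred = pred))
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       pred = pred,
       left = grow_tree(X, y, left, depth_left - 1L, mtry, task, min_node, env),
       right = grow_tree(X, y, right, depth_left - 1L, mtry, task, min_node, env))
}

#' Fit the guiding tree ensemble
#'
#' Fits `n_trees` depth-limited CART trees on bootstrap resamples with
#' square-root feature subsampling at each node, and records the set of
#' features used in each tree's split nodes. These sets define the MLP
#' connectivity.
#'
#' @param X numeric feature matrix (n x p), no missing values.
#' @param y labels: 0/1 for classification, numeric for regression.
#' @param spec a [tree_ensemble_spec()].
#' @param task `"classification"` or `"regression"`.
#' @param min_node minimum leaf size (default 2).
#' @return the fitted `tree_ensemble_spec` (fields `trees`, `used_features`).
#' @export
fit_tree_ensemble <- function(X, y, spec, task = "classification",
                              min_node = 2L) {
  stopifnot(inherits(spec, "tree_ensemble_spec"), nrow(X) >= 2L,
            nrow(X) == length(y))
  if (task == "classification" && length(unique(y)) < 2L) {
    stop("single-class labels: cannot fit classification trees")
  }
  n <- nrow(X); p <- ncol(X)
  mtry <- max(1L, as.integer(ceiling(sqrt(p))))
  with_local_seed(spec$seed, {
    trees <- vector("list", spec$n_trees)
    used <- vector("list", spec$n_trees)
    for (t in seq_len(spec$n_trees)) {
      for (try in 1:20) {
        rows <- sample.int(n, n, replace = TRUE)
        if (task != "classification" || length(unique(y[rows])) > 1L) break
      }
      env <- new.env(); env$used <- integer(0)
      trees[[t]] <- grow_tree(X, y, rows, spec$depth, mtry, task, min_node, env)
      used[[t]] <- sort(unique(env$used))
    }
    spec$trees <- trees
    spec$used_features <- used
  })
  spec
}

#' Connectivity mask from a fitted ensemble
#'
#' One hidden unit per tree; row `j` has ones exactly at the features used by
#' tree `j`'s splits (a degenerate tree with no splits connects to nothing).
#'
#' @param ensemble fitted [tree_ensemble_spec()].
#' @param n_features number of input features.
#' @return binary matrix `n_trees x n_features`.
#' @export
build_mask <- function(ensemble, n_features) {
  stopifnot(inherits(ensemble, "tree_ensemble_spec"),
            !is.null(ensemble$used_features))
  mask <- matrix(0, nrow = ensemble$n_trees, ncol = n_features)
  for (j in seq_len(ensemble$n_trees)) {
    f <- ensemble$used_features[[j]]
    if (length(f)) {
      stopifnot(max(f) <= n_features)
      mask[j, f] <- 1
    }
  }
  mask
}

#' Construct an (untrained) sparse MLP
#'
#' @param mask connectivity mask from [build_mask()].
#' @param task `"classification"` or `"regression"`.
#' @param config list of training settings: `ridge` (default 1e-3),
#'   `learning_rate` (1e-3), `max_epochs` (500), `patience` (10),
#'   `seed` (1).
#' @return object of class `sparse_mlp` (weights initialized, masked
#'   positions exactly zero).
#' @export
sparse_mlp <- function(mask, task = c("classification", "regression"),
                       config = list()) {
  task <- match.arg(task)
  stopifnot(is.matrix(mask), all(mask %in% c(0, 1)))
  cfg <- utils::modifyList(
    list(ridge = 1e-3, learning_rate = 1e-3, max_epochs = 500L,
         patience = 10L, seed = 1L), config)
  h <- nrow(mask); p <- ncol(mask)
  with_local_seed(cfg$seed, {
    fan_in <- pmax(1, rowSums(mask))
    W1 <- matrix(stats::rnorm(h * p), h, p) / sqrt(fan_in) * mask
    w2 <- stats::rnorm(h) / sqrt(h)
  })
  structure(list(mask = mask, W1 = W1, b1 = rep(0, h), w2 = w2, b2 = 0,
                 task = task, config = cfg, class_weights = NULL,
                 center = NULL, scale = NULL, trained = FALSE,
                 loss_history = NULL),
            class = "sparse_mlp")
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

mlp_forward <- function(model, X) {
  Z <- X %*% t(model$W1)
  Z <- sweep(Z, 2L, model$b1, `+`)
  A <- relu(Z)
  s <- drop(A %*% model$w2) + model$b2
  list(Z = Z, A = A, score = s)
}

mlp_loss <- function(model, X, y, sample_w, penalize = TRUE) {
  fw <- mlp_forward(model, X)
  if (model$task == "classification") {
    pr <- sigmoid(fw$score)
    eps <- 1e-12
    data_loss <- mean(sample_w * -(y * log(pr + eps) + (1 - y) * log(1 - pr + eps)))
  } else {
    data_loss <- mean((fw$score - y)^2)
  }
  if (penalize) {
    data_loss <- data_loss +
      model$config$ridge * (sum(model$W1^2) + sum(model$w2^2))
  }
  data_loss
}

#' Train a sparse MLP
#'
#' Full-batch Adam on the masked weights only. Classification uses
#' class-weighted cross-entropy with weights \eqn{w_c = n/(K n_c)} (inversely
#' proportional to class frequency); regression uses mean squared error. A
#' ridge penalty is added to both. Training stops when the validation loss
#' has not improved for `patience` (10) consecutive epochs; the best-epoch
#' weights are restored.
#'
#' @param model a [sparse_mlp()].
#' @param X_train,y_train training data (features already z-scored).
#' @param X_val,y_val validation data for early stopping (same scaling).
#' @return the trained `sparse_mlp`, with `loss_history` (data.frame of
#'   train/validation loss per epoch) and `best_epoch` recorded.
#' @export
train_sparse_mlp <- function(model, X_train, y_train, X_val, y_val) {
  stopifnot(inherits(model, "sparse_mlp"), nrow(X_train) == length(y_train))
  if (is.null(X_val) || nrow(X_val) == 0L) stop("empty validation set")
  cfg <- model$config
  n <- nrow(X_train)
  if (model$task == "classification") {
    counts <- table(factor(y_train, levels = c(0, 1)))
    cw <- as.numeric(n / (2 * pmax(counts, 1L)))
    model$class_weights <- stats::setNames(cw, c("0", "1"))
    sw_train <- cw[y_train + 1L]
    sw_val <- cw[y_val + 1L]
  } else {
    sw_train <- rep(1, n); sw_val <- rep(1, length(y_val))
  }

  params <- c("W1", "b1", "w2", "b2")
  m <- v <- lapply(model[params], function(p) p * 0)
  names(m) <- names(v) <- params
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  best <- list(loss = Inf, weights = model[params], epoch = 0L)
  wait <- 0L
  hist_train <- hist_val <- numeric(0)

  for (epoch in seq_len(cfg$max_epochs)) {
    fw <- mlp_forward(model, X_train)
    if (model$task == "classification") {
      dscore <- sw_train * (sigmoid(fw$score) - y_train) / n
    } else {
      dscore <- 2 * (fw$score - y_train) / n
    }
    if (any(!is.finite(dscore))) stop("non-finite loss gradient")
    grad <- list(
      W1 = ((t(fw$A > 0) * (model$w2 %o% dscore)) %*% X_train) * model$mask +
        2 * cfg$ridge * model$W1,
      b1 = drop((t(fw$A > 0) * (model$w2 %o% dscore)) %*% rep(1, n)),
      w2 = drop(t(fw$A) %*% dscore) + 2 * cfg$ridge * model$w2,
      b2 = sum(dscore)
    )
    for (pn in params) {
      m[[pn]] <- beta1 * m[[pn]] + (1 - beta1) * grad[[pn]]
      v[[pn]] <- beta2 * v[[pn]] + (1 - beta2) * grad[[pn]]^2
      mh <- m[[pn]] / (1 - beta1^epoch)
      vh <- v[[pn]] / (1 - beta2^epoch)
      model[[pn]] <- model[[pn]] - cfg$learning_rate * mh / (sqrt(vh) + adam_eps)
    }
    model$W1 <- model$W1 * model$mask  # structural zeros stay exactly zero

    tl <- mlp_loss(model, X_train, y_train, sw_train)
    vl <- mlp_loss(model, X_val, y_val, sw_val)
    if (!is.finite(tl) || !is.finite(vl)) stop("non-finite loss")
    hist_train <- c(hist_train, tl); hist_val <- c(hist_val, vl)
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, weights = model[params], epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model[params] <- best$weights
  model$trained <- TRUE
  model$best_epoch <- best$epoch
  model$loss_history <- data.frame(epoch = seq_along(hist_train),
                                   train = hist_train, validation = hist_val)
  model
}

#' Predict from a sparse MLP
#'
#' @param object a trained [sparse_mlp()].
#' @param newdata numeric matrix with the model's feature dimension (already
#'   z-scored with the training parameters).
#' @param ... unused.
#' @return classification: probability-like scores in \[0, 1\]; regression:
#'   real-valued predictions.
#' @export
predict.sparse_mlp <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  if (ncol(newdata) != ncol(object$mask)) {
    stop("feature dimension mismatch: model expects ", ncol(object$mask),
         ", got ", ncol(newdata))
  }
  s <- mlp_forward(object, newdata)$score
  if (object$task == "classification") sigmoid(s) else s
}

#' Feature importance by connection counting
#'
#' The importance of a feature is the number of hidden units (trees) whose
#' connectivity row includes it.
#'
#' @param model a [sparse_mlp()] (trained or not; importance is structural).
#' @return integer vector of per-feature connection counts.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "sparse_mlp"))
  as.integer(colSums(model$mask))
}

#' Number of trainable parameters
#'
#' @param model a [sparse_mlp()].
#' @return count of unmasked weights plus biases; at most the dense
#'   equivalent `h*p + h + h + 1`.
#' @export
n_parameters <- function(model) {
  sum(model$mask) + length(model$b1) + length(model$w2) + 1L
}

#' Grid search over ensemble size and depth
#'
#' Fits one tree ensemble + sparse MLP per grid cell on the training split
#' and scores it on the validation split (AUC for classification, negative
#' RMSE for regression); returns the argmax. Ties are broken toward fewer
#' trees, then smaller depth. Per-cell failures are recorded and skipped
#' unless every cell fails.
#'
#' @param X_train,y_train,X_val,y_val z-scored training and validation data.
#' @param trees_grid,depth_grid candidate values (defaults: the study grid).
#' @param task `"classification"` or `"regression"`.
#' @param config training config passed to [sparse_mlp()].
#' @param seed seed for tree fitting and weight initialization.
#' @return list with `spec` (winning [tree_ensemble_spec()]), `model`
#'   (trained `sparse_mlp`), `score`, and `results` (per-cell data.frame).
#' @export
grid_search <- function(X_train, y_train, X_val, y_val,
                        trees_grid = c(10, 20, 40, 60, 80, 100),
                        depth_grid = c(4, 6, 8, 10),
                        task = "classification", config = list(), seed = 1L) {
  stopifnot(length(trees_grid) >= 1L, length(depth_grid) >= 1L)
  cells <- expand.grid(n_trees = sort(trees_grid), depth = sort(depth_grid))
  cells <- cells[order(cells$n_trees, cells$depth), ]
  res <- data.frame(n_trees = cells$n_trees, depth = cells$depth,
                    score = NA_real_, error = NA_character_)
  best <- NULL
  for (i in seq_len(nrow(cells))) {
    fit <- tryCatch({
      spec <- tree_ensemble_spec(cells$n_trees[i], cells$depth[i], seed = seed)
      spec <- fit_tree_ensemble(X_train, y_train, spec, task)
      model <- sparse_mlp(build_mask(spec, ncol(X_train)), task,
                          utils::modifyList(config, list(seed = seed)))
      model <- train_sparse_mlp(model, X_train, y_train, X_val, y_val)
      sc <- if (task == "classification") {
        auc_roc(predict(model, X_val), y_val)$auc
      } else {
        -sqrt(mean((predict(model, X_val) - y_val)^2))
      }
      list(spec = spec, model = model, score = sc)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      res$error[i] <- conditionMessage(fit)
      next
    }
    res$score[i] <- fit$score
    # strict > keeps the earliest (smallest) cell on exact ties
    if (is.null(best) || fit$score > best$score + 1e-12) best <- fit
  }
  if (is.null(best)) stop("all grid cells failed; first error: ",
                          res$error[!is.na(res$error)][1])
  c(best, list(results = res))
}
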