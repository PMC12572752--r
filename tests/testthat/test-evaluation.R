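test_that("make_split is stratified, disjoint, exhaustive and deterministic", {
  manifest <- data.frame(id = sprintf("p%02d", 1:20),
                         group = rep(c("patient", "control"), each = 10))
  plan <- make_split(manifest, 0.8, seed = 1)
  expect_length(plan$train, 16L)
  expect_length(plan$test, 4L)
  tg <- manifest$group[manifest$id %in% plan$train]
  expect_equal(sum(tg == "patient"), 8L)
  expect_identical(make_split(manifest, 0.8, seed = 1), plan)

  for (s in 1:100) {
    p <- make_split(manifest, 0.8, seed = s)
    expect_length(intersect(p$train, p$test), 0L)
    expect_setequal(c(p$train, p$test), manifest$id)
  }
  small <- data.frame(id = c("a", "b", "c"), group = c("patient", "control",
                                                       "control"))
  expect_error(make_split(small), "too small")
})

test_that("z-scoring uses train parameters only and drops constants", {
  set.seed(4)
  train <- matrix(rnorm(200, mean = 5, sd = 2), 50, 4,
                  dimnames = list(NULL, paste0("f", 1:4)))
  test <- matrix(rnorm(80, mean = 9, sd = 2), 20, 4,
                 dimnames = list(NULL, paste0("f", 1:4)))
  zs <- zscore_fit_transform(train, test)
  expect_lt(max(abs(colMeans(zs$train))), 1e-9)
  expect_lt(max(abs(apply(zs$train, 2, sd) - 1)), 1e-9)
  # test set transformed with train parameters: its means are NOT zero
  expect_gt(min(abs(colMeans(zs$test))), 0.5)
  expect_equal(zs$test, sweep(sweep(test, 2, colMeans(train)), 2,
                              apply(train, 2, sd), `/`))
  train2 <- cbind(train, const = 7)
  expect_warning(zs2 <- zscore_fit_transform(train2), "constant")
  expect_false("const" %in% colnames(zs2$train))
})

test_that("early fusion aligns rows by id and rejects mismatches", {
  a <- data.frame(id = c("x", "y", "z"), timing__a = 1:3)
  b <- data.frame(id = c("z", "x", "y"), lexsem__b = c(30, 10, 20))
  fused <- early_fusion(a, b)
  expect_equal(dim(fused), c(3L, 3L))
  expect_equal(fused$lexsem__b, c(10, 20, 30))  # realigned to a's order
  expect_error(early_fusion(a, data.frame(id = c("x", "y", "q"),
                                          lexsem__b = 1:3)), "id sets differ")
})

test_that("AUC equals the exhaustive pair-counting (rank-sum) oracle", {
  expect_equal(auc_roc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1)
  set.seed(15)
  for (i in 1:25) {
    n <- sample(8:50, 1)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels <- c(0, 1, labels[-(1:2)])
    scores <- sample(round(rnorm(n), 1))  # coarse grid forces ties
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc_roc(scores, labels)$auc, mean(pairs), tolerance = 1e-12)
    roc <- auc_roc(scores, labels)$roc
    expect_equal(roc[1, ], data.frame(fpr = 0, tpr = 0))
    expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    # AUC equals the trapezoidal area of its own ROC
    expect_equal(auc_roc(scores, labels)$auc,
                 sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2),
                 tolerance = 1e-9)
  }
  expect_error(auc_roc(1:4, rep(1, 4)), "both classes")
})

test_that("large-sample AUC of uninformative scores is near 1/2", {
  set.seed(21)
  expect_lt(abs(auc_roc(rnorm(4000), rep(0:1, 2000))$auc - 0.5), 0.05)
})

test_that("DeLong placements match brute force; self-comparison degenerates", {
  set.seed(16)
  labels <- rep(c(0, 1), c(12, 10))
  sa <- rnorm(22) + labels
  sb <- rnorm(22) + 0.8 * labels
  # brute-force placement values
  pos <- which(labels == 1); neg <- which(labels == 0)
  v_pos <- sapply(pos, function(i)
    mean((sa[i] > sa[neg]) + 0.5 * (sa[i] == sa[neg])))
  pl <- speechmark:::delong_placements(sa, labels)
  expect_equal(pl$v_pos, v_pos, tolerance = 1e-12)
  expect_equal(pl$auc, auc_roc(sa, labels)$auc, tolerance = 1e-12)

  dl <- delong_test(sa, sb, labels)
  expect_false(dl$degenerate)
  expect_equal(dl$delta_auc, auc_roc(sa, labels)$auc - auc_roc(sb, labels)$auc)
  self <- delong_test(sa, sa, labels)
  expect_true(self$degenerate)
  expect_equal(self$p, 1)
  expect_equal(self$delta_auc, 0)
})

test_that("regression metrics match direct formulas", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(regression_metrics(x, x)$spearman_rho, 1)
  expect_equal(regression_metrics(x, x)$rmse, 0)
  y <- rank(-x)  # exactly reversed ranks
  expect_equal(regression_metrics(x, y)$spearman_rho, -1)

  set.seed(17)
  p <- rnorm(15); a <- rnorm(15)
  m <- regression_metrics(p, a)
  rp <- rank(p); ra <- rank(a)
  rho <- sum((rp - mean(rp)) * (ra - mean(ra))) /
    sqrt(sum((rp - mean(rp))^2) * sum((ra - mean(ra))^2))
  expect_equal(m$spearman_rho, rho, tolerance = 1e-9)
  expect_equal(m$rmse, sqrt(sum((p - a)^2) / 15), tolerance = 1e-9)
  expect_true(regression_metrics(rep(2, 5), 1:5)$degenerate)
})

test_that("median imputation fills from train and drops all-NA columns", {
  train <- cbind(a = c(1, NA, 3), b = c(NA, NA, NA), c = c(2, 4, 6))
  test <- cbind(a = c(NA, 5), b = c(1, 2), c = c(NA, 1))
  imp <- impute_median(train, test)
  expect_equal(imp$dropped, "b")
  expect_equal(imp$test[1, "a"], c(a = 2))  # train median, not test's
  expect_equal(imp$test[1, "c"], c(c = 4))
})
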