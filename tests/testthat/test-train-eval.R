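# Confusion counts, scalar metrics, ROC/AUC, splits, early stopping,
# cross-validation, and the grid search.

test_that("confusion counts the four cells exactly", {
  cc <- confusion(c(1, 0), c(1, 0))
  expect_identical(unclass(cc)[c("TP", "FP", "TN", "FN")],
                   list(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  # fully wrong predictions: no true cells
  cw <- confusion(c(0, 1, 0), c(1, 0, 1))
  expect_identical(cw$TP + cw$TN, 0L)
  # conservation on random inputs
  set.seed(21)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    pred <- sample(0:1, n, TRUE); truth <- sample(0:1, n, TRUE)
    cc <- confusion(pred, truth)
    expect_identical(cc$TP + cc$FP + cc$TN + cc$FN, n)
    expect_identical(cc$TP + cc$FN, sum(truth == 1))
    expect_identical(cc$TN + cc$FP, sum(truth == 0))
  }
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "length")
  expect_error(confusion(c(1, 2), c(1, 0)), "labels")
})

test_that("metrics satisfy their identities and edge conventions", {
  # perfect prediction
  m <- compute_metrics(confusion_counts(TP = 5, FP = 0, TN = 7, FN = 0))
  expect_equal(c(m$Q, m$SE, m$SP, m$MCC), c(1, 1, 1, 1))
  # MCC zero-denominator convention
  m0 <- compute_metrics(confusion_counts(TP = 0, FP = 0, TN = 5, FN = 5))
  expect_identical(m0$MCC, 0)
  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0)), "zero")
  # Q n = TP + TN and the prevalence-weighted identity; MCC class-swap
  set.seed(22)
  for (i in 1:25) {
    cc <- confusion_counts(TP = sample(0:20, 1), FP = sample(0:20, 1),
                           TN = sample(1:20, 1), FN = sample(0:20, 1))
    m <- compute_metrics(cc)
    expect_equal(m$Q * m$n, cc$TP + cc$TN, tolerance = 1e-12)
    P <- cc$TP + cc$FN; N <- cc$TN + cc$FP
    if (P > 0 && N > 0)
      expect_equal(m$Q, (m$SE * P + m$SP * N) / (P + N), tolerance = 1e-12)
    sw <- compute_metrics(confusion_counts(TP = cc$TN, FP = cc$FN,
                                           TN = cc$TP, FN = cc$FP))
    expect_equal(sw$MCC, m$MCC, tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with the pairwise oracle, pROC, and the trapezoid", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 8), rep(c(0, 1), 4))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 0, 1, 0))$auc, 1)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
  set.seed(23)
  for (i in 1:20) {
    n <- sample(8:40, 1)
    truth <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- round(runif(n), 2)   # coarse grid forces ties
    r <- roc_auc(scores, truth)
    expect_equal(r$auc, pairwise_auc(scores, truth), tolerance = 1e-12)
    # trapezoidal area under the swept ROC equals the rank statistic
    o <- order(r$roc$fpr, r$roc$tpr)
    fpr <- r$roc$fpr[o]; tpr <- r$roc$tpr[o]
    trap <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    expect_lt(abs(trap - r$auc), 1e-9)
    # reversing the scores complements the AUC
    expect_equal(roc_auc(-scores, truth)$auc, 1 - r$auc, tolerance = 1e-12)
    # cross-check against an independent implementation
    pr <- suppressMessages(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                               direction = "<")))
    expect_equal(r$auc, as.numeric(pr), tolerance = 1e-12)
  }
})

test_that("the stratified split is disjoint, exhaustive, and reproducible", {
  set.seed(24)
  y <- sample(0:1, 100, TRUE, prob = c(0.6, 0.4))
  sp <- split_train_val(y, fraction = 0.2, seed = 7L)
  expect_length(sp$val, 20L)
  expect_length(sp$train, 80L)
  expect_identical(sort(c(sp$train, sp$val)), 1:100)
  sp2 <- split_train_val(y, fraction = 0.2, seed = 7L)
  expect_identical(sp, sp2)
  # stratification: class balance preserved within 1 sample per class
  expect_equal(sum(y[sp$val] == 1), round(sum(y == 1) * 0.2), tolerance = 1)
  expect_error(split_train_val(c(0, 1, 0), 0.2, 1L), "at least 5")
})

test_that("early stopping fires on stalls and restores the best epoch", {
  cfg <- early_stop_config(patience = 1L)
  r <- check_early_stop(c(0.30, 0.28, 0.29), cfg)
  expect_true(r$stop)
  expect_identical(r$best_epoch, 2L)
  # strictly decreasing errors never stop
  expect_false(check_early_stop(seq(0.5, 0.1, by = -0.1), cfg)$stop)
  # single epoch never stops
  expect_false(check_early_stop(0.4, cfg)$stop)
  # a tie counts as no improvement
  expect_true(check_early_stop(c(0.3, 0.3), cfg)$stop)
  # patience 2 tolerates one stall
  cfg2 <- early_stop_config(patience = 2L)
  expect_false(check_early_stop(c(0.30, 0.28, 0.29), cfg2)$stop)
  expect_true(check_early_stop(c(0.30, 0.28, 0.29, 0.285), cfg2)$stop)
  expect_error(check_early_stop(numeric(0), cfg), "empty")
})

# Cheap deterministic factory for harness tests: logistic regression on the
# informative columns.
logit_factory <- function(tx, ty, s) {
  df <- data.frame(y = ty, tx[, c(1:10, 167:169)])
  fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                     family = stats::binomial()))
  structure(list(fit = fit), class = "test_logit")
}
predict.test_logit <- function(object, newdata, ...) {
  p <- stats::predict(object$fit,
                      newdata = as.data.frame(newdata[, c(1:10, 167:169)]),
                      type = "response")
  data.frame(label = as.integer(p > 0.5), score = as.numeric(p))
}

test_that("cross-validation partitions the data and summarizes folds", {
  ds <- generate_dataset(synthetic_spec(n_samples = 200L, separation = 2,
                                        seed = 25L))
  assign("predict.test_logit", predict.test_logit, envir = globalenv())
  on.exit(rm("predict.test_logit", envir = globalenv()), add = TRUE)
  cv <- kfold_cv(logit_factory, ds$features, ds$labels, k = 5L, seed = 9L)
  expect_length(cv$folds, 5L)
  # every sample validated exactly once
  ns <- vapply(cv$folds, function(f) f$metrics$n, 0)
  expect_identical(sum(ns), 200)
  expect_lte(diff(range(ns)), 1)
  # summary mean equals the arithmetic mean of the fold metrics
  qs <- vapply(cv$folds, function(f) f$metrics$Q, 0)
  expect_equal(cv$summary$mean[cv$summary$metric == "Q"], mean(qs))
  expect_equal(cv$summary$sd[cv$summary$metric == "Q"], stats::sd(qs))
  expect_error(kfold_cv(logit_factory, ds$features[1:3, ], ds$labels[1:3],
                        k = 5L), "at least")
})

test_that("grid search ranks every configuration by mean accuracy", {
  ds <- generate_dataset(synthetic_spec(n_samples = 150L, separation = 2,
                                        seed = 26L))
  assign("predict.test_logit", predict.test_logit, envir = globalenv())
  on.exit(rm("predict.test_logit", envir = globalenv()), add = TRUE)
  # config 2 is deliberately crippled (scrambled labels)
  factory <- function(cfg, tx, ty, s) {
    if (cfg$scramble) ty <- sample(ty)
    logit_factory(tx, ty, s)
  }
  set.seed(27)
  gs <- grid_search(list(list(scramble = FALSE), list(scramble = TRUE)),
                    factory, ds$features, ds$labels, k = 3L, seed = 9L)
  expect_identical(sort(gs$ranking$config), 1:2)
  expect_identical(gs$ranking$config[1], 1L)
  expect_true(all(diff(gs$ranking$mean_Q) <= 0))
  expect_error(grid_search(list(), factory, ds$features, ds$labels), "empty")
})

test_that("evaluate_model reports metrics with AUC and ROC points", {
  ds <- generate_dataset(synthetic_spec(n_samples = 120L, separation = 2,
                                        seed = 28L))
  assign("predict.test_logit", predict.test_logit, envir = globalenv())
  on.exit(rm("predict.test_logit", envir = globalenv()), add = TRUE)
  fit <- logit_factory(ds$features, ds$labels, 1L)
  mt <- evaluate_model(fit, ds$features, ds$labels)
  expect_s3_class(mt, "metrics_report")
  expect_true(mt$AUC > 0.5)
  expect_true(all(c("fpr", "tpr") %in% names(attr(mt, "roc"))))
})
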