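# Model assessment (confusion counts, accuracy/sensitivity/specificity/MCC,
# rank-based ROC/AUC) and the training harness: stratified train/validation
# splits, early stopping, stratified k-fold cross-validation and a
# hyperparameter grid search.

#' Confusion counts for binary predictions
#'
#' The positive class is 1 (hERG blocker).
#'
#' @param pred,truth Integer vectors of 0/1 labels, equal length.
#' @return A list of class \code{confusion_counts} with \code{TP},
#'   \code{FP}, \code{TN}, \code{FN}.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length")
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("labels must be 0 or 1")
  structure(list(
    TP = sum(pred == 1 & truth == 1),
    FP = sum(pred == 1 & truth == 0),
    TN = sum(pred == 0 & truth == 0),
    FN = sum(pred == 0 & truth == 1)), class = "confusion_counts")
}

#' Confusion counts from explicit cell values
#'
#' @param TP,FP,TN,FN Non-negative integer counts.
#' @return A \code{confusion_counts} list.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN),
            class = "confusion_counts")
}

#' Scalar classification metrics from confusion counts
#'
#' Accuracy \eqn{Q = (TP+TN)/(TP+FP+TN+FN)}, sensitivity
#' \eqn{SE = TP/(TP+FN)}, specificity \eqn{SP = TN/(FP+TN)}, and the
#' Matthews correlation coefficient
#' \eqn{MCC = (TP \cdot TN - FP \cdot FN) / \sqrt{(FP+TN)(FP+TP)(FN+TN)(FN+TP)}},
#' with MCC set to 0 when any factor of the denominator is 0.
#'
#' @param cc A \code{\link{confusion_counts}} object (or a list with fields
#'   TP, FP, TN, FN).
#' @return A list of class \code{metrics_report} with \code{Q}, \code{SE},
#'   \code{SP}, \code{MCC} (and \code{n}).
#' @export
compute_metrics <- function(cc) {
  n <- cc$TP + cc$FP + cc$TN + cc$FN
  if (n < 1) stop("confusion counts are all zero")
  Q <- (cc$TP + cc$TN) / n
  SE <- if (cc$TP + cc$FN > 0) cc$TP / (cc$TP + cc$FN) else NA_real_
  SP <- if (cc$FP + cc$TN > 0) cc$TN / (cc$FP + cc$TN) else NA_real_
  den <- (cc$FP + cc$TN) * (cc$FP + cc$TP) * (cc$FN + cc$TN) * (cc$FN + cc$TP)
  MCC <- if (den == 0) 0 else
    (cc$TP * cc$TN - cc$FP * cc$FN) / sqrt(den)
  structure(list(Q = Q, SE = SE, SP = SP, MCC = MCC, n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Q = %.1f%%  SE = %.1f%%  SP = %.1f%%  MCC = %.3f  (n = %d)\n",
              100 * x$Q, 100 * x$SE, 100 * x$SP, x$MCC, x$n))
  if (!is.null(x$AUC)) cat(sprintf("AUC = %.3f\n", x$AUC))
  invisible(x)
}

#' ROC curve and AUC
#'
#' AUC is computed from the rank statistic: the probability that a random
#' positive outscores a random negative, with ties counted one half. ROC
#' points come from a threshold sweep over the unique scores.
#'
#' @param scores Positive-class scores (higher = more blocker-like).
#' @param truth Binary labels; both classes must be present.
#' @return List with \code{auc} and \code{roc}, a data.frame of
#'   \code{threshold}, \code{fpr}, \code{tpr}.
#' @export
roc_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth), all(truth %in% c(0, 1)))
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present for ROC/AUC")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(scores >= t & truth == 0) / n0, 0),
    tpr = vapply(thr, function(t) sum(scores >= t & truth == 1) / n1, 0))
  list(auc = auc, roc = roc)
}

#' Stratified train/validation split
#'
#' @param labels Binary label vector (the data are addressed by index).
#' @param fraction Validation fraction (default 1/5, i.e. a 4:1 split).
#' @param seed Integer seed.
#' @return List with integer index vectors \code{train} and \code{val};
#'   disjoint, exhaustive, stratified by class.
#' @export
split_train_val <- function(labels, fraction = 0.2, seed = 1L) {
  n <- length(labels)
  if (n < 5L) stop("need at least 5 samples to split")
  stopifnot(fraction > 0, fraction < 1)
  set.seed(seed)
  val <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    k <- max(1L, round(length(idx) * fraction))
    val <- c(val, sample(idx, k))
  }
  val <- sort(val)
  list(train = setdiff(seq_len(n), val), val = val)
}

#' Early-stopping configuration
#'
#' @param fraction Validation fraction held out when no validation set is
#'   supplied (default 1/5).
#' @param patience Number of consecutive epochs without improvement of the
#'   validation error tolerated before stopping. The default of 5 rides out
#'   the transient loss fluctuations of adaptive-moment optimization on the
#'   initial plateau; a patience of 1 stops at the first non-improving
#'   epoch.
#' @param min_delta Minimum decrease counting as an improvement.
#' @return A list of class \code{early_stop_config}.
#' @export
early_stop_config <- function(fraction = 0.2, patience = 5L, min_delta = 0) {
  stopifnot(fraction > 0, fraction < 1, patience >= 1, min_delta >= 0)
  structure(list(fraction = fraction, patience = as.integer(patience),
                 min_delta = min_delta), class = "early_stop_config")
}

#' Early-stopping decision
#'
#' Stops when the validation error has not improved on its running best for
#' \code{patience} consecutive epochs; the caller restores the parameters of
#' the best epoch.
#'
#' @param val_errors Per-epoch validation errors observed so far.
#' @param cfg An \code{\link{early_stop_config}}.
#' @return List with \code{stop} (logical) and \code{best_epoch}.
#' @export
check_early_stop <- function(val_errors, cfg = early_stop_config()) {
  if (length(val_errors) == 0L) stop("history is empty")
  best_err <- Inf; best_epoch <- 0L; since <- 0L
  for (e in seq_along(val_errors)) {
    if (val_errors[e] < best_err - cfg$min_delta) {
      best_err <- val_errors[e]; best_epoch <- e; since <- 0L
    } else {
      since <- since + 1L
    }
  }
  list(stop = since >= cfg$patience, best_epoch = best_epoch)
}

# Stratified fold assignment: returns an integer vector of fold ids. The
# round-robin counter continues across classes so total fold sizes differ by
# at most one while each class stays balanced across folds.
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  folds <- integer(length(labels))
  off <- 0L
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- ((seq_along(idx) - 1L + off) %% k) + 1L
    off <- (off + length(idx)) %% k
  }
  folds
}

#' Stratified k-fold cross-validation
#'
#' Each fold is held out once; the model factory trains on the remaining
#' folds and its predictions on the held-out fold give per-fold confusion
#' counts and metrics, summarized by mean and standard deviation.
#'
#' @param model_factory Function \code{(train_x, train_y, seed)} returning a
#'   fitted object whose \code{predict(object, x)} yields a data.frame with
#'   \code{label} and \code{score} columns.
#' @param x Feature matrix.
#' @param y Binary labels.
#' @param k Number of folds (default 5).
#' @param seed Integer seed (fold assignment and per-fold training seeds).
#' @return List with \code{folds} (per-fold list of \code{fold},
#'   \code{counts}, \code{metrics}, \code{auc}) and \code{summary}
#'   (data.frame of mean and sd for Q, SE, SP, MCC, AUC).
#' @export
kfold_cv <- function(model_factory, x, y, k = 5L, seed = 1L) {
  x <- as.matrix(x); y <- as.integer(y)
  n <- nrow(x)
  if (n < k) stop("need at least k samples")
  fold_id <- stratified_folds(y, k, seed)
  res <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold_id != f
    fit <- model_factory(x[tr, , drop = FALSE], y[tr], seed + f)
    pr <- predict(fit, x[!tr, , drop = FALSE])
    cc <- confusion(pr$label, y[!tr])
    mt <- compute_metrics(cc)
    auc <- tryCatch(roc_auc(pr$score, y[!tr])$auc, error = function(e) NA_real_)
    res[[f]] <- list(fold = f, counts = cc, metrics = mt, auc = auc)
  }
  num <- function(get) vapply(res, get, 0)
  tab <- data.frame(
    metric = c("Q", "SE", "SP", "MCC", "AUC"),
    mean = c(mean(num(function(r) r$metrics$Q)),
             mean(num(function(r) r$metrics$SE)),
             mean(num(function(r) r$metrics$SP)),
             mean(num(function(r) r$metrics$MCC)),
             mean(num(function(r) r$auc))),
    sd = c(stats::sd(num(function(r) r$metrics$Q)),
           stats::sd(num(function(r) r$metrics$SE)),
           stats::sd(num(function(r) r$metrics$SP)),
           stats::sd(num(function(r) r$metrics$MCC)),
           stats::sd(num(function(r) r$auc))))
  list(folds = res, summary = tab)
}

#' Hyperparameter grid search by cross-validation
#'
#' Every configuration is scored by stratified k-fold cross-validation and
#' ranked by mean accuracy Q, ties broken by mean MCC and then declaration
#' order.
#'
#' @param configs List of configuration objects (passed to the factory).
#' @param model_factory Function \code{(config, train_x, train_y, seed)}
#'   returning a fitted object with a \code{predict} method as in
#'   \code{\link{kfold_cv}}.
#' @param x,y Features and labels.
#' @param k Folds.
#' @param seed Integer seed.
#' @return List with \code{ranking} (data.frame: config index, mean Q, mean
#'   MCC, sd of Q, ordered best first) and \code{results} (per-config
#'   \code{\link{kfold_cv}} outputs).
#' @export
grid_search <- function(configs, model_factory, x, y, k = 5L, seed = 1L) {
  if (length(configs) == 0L) stop("the grid is empty")
  results <- vector("list", length(configs))
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    factory <- function(tx, ty, s) model_factory(cfg, tx, ty, s)
    results[[ci]] <- kfold_cv(factory, x, y, k = k, seed = seed)
  }
  meanQ <- vapply(results, function(r) r$summary$mean[r$summary$metric == "Q"], 0)
  meanM <- vapply(results, function(r) r$summary$mean[r$summary$metric == "MCC"], 0)
  sdQ <- vapply(results, function(r) r$summary$sd[r$summary$metric == "Q"], 0)
  ord <- order(-meanQ, -meanM, seq_along(configs))
  ranking <- data.frame(config = ord, mean_Q = meanQ[ord],
                        mean_MCC = meanM[ord], sd_Q = sdQ[ord])
  list(ranking = ranking, results = results)
}

#' Evaluate a model on labeled data
#'
#' @param object A fitted model with a \code{predict} method returning
#'   \code{label} and \code{score}.
#' @param x Feature matrix.
#' @param y Binary labels.
#' @return A \code{metrics_report} with an additional \code{AUC} field and
#'   the ROC points attached as attribute \code{"roc"}.
#' @export
evaluate_model <- function(object, x, y) {
  pr <- predict(object, x)
  mt <- compute_metrics(confusion(pr$label, as.integer(y)))
  rc <- tryCatch(roc_auc(pr$score, as.integer(y)), error = function(e) NULL)
  if (!is.null(rc)) {
    mt$AUC <- rc$auc
    attr(mt, "roc") <- rc$roc
  }
  mt
}
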