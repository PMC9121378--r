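# Evaluation: ROC curves, AUC, threshold selection and cross-validation.
#
# Conventions used throughout: a prediction is positive when the score is
# strictly greater than the threshold; candidate thresholds for threshold
# selection are the midpoints between adjacent distinct scores plus the
# extremes (-Inf = everything positive, max(scores) = everything negative).

#' ROC curve and area under it
#'
#' `roc_curve()` sweeps every distinct score value from high to low and
#' records the (false-positive rate, true-positive rate) operating point
#' reached once all observations scoring at least that value are called
#' positive; the leading row is the all-negative point (0, 0) at threshold
#' `Inf`. `roc_auc()` integrates the curve by the trapezoid rule, which for
#' this construction equals the Mann-Whitney pairwise statistic
#' `P(score_pos > score_neg) + 0.5 P(tie)` exactly.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1 = positive); both classes must be present.
#' @return `roc_curve()`: data.frame with columns `threshold`, `fpr`, `tpr`
#'   (fpr non-decreasing). `roc_auc()`: object of class `"roc_eval"` with
#'   `auc` and `points`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc  # 1
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))$auc  # 0.75
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L)
    stop("ROC needs both classes present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp_end <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(1L - y)[grp_end]
  data.frame(threshold = c(Inf, s[grp_end]),
             fpr = c(0, fp / N),
             tpr = c(0, tp / P))
}

#' @rdname roc_curve
#' @export
roc_auc <- function(scores, labels) {
  pts <- roc_curve(scores, labels)
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(auc = auc, points = pts), class = "roc_eval")
}

#' @export
print.roc_eval <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f over %d operating points\n",
              x$auc, nrow(x$points)))
  invisible(x)
}

.candidate_thresholds <- function(scores) {
  u <- sort(unique(scores))
  mids <- if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  c(-Inf, mids, u[length(u)])
}

.sens_spec_at <- function(scores, labels, threshold) {
  pred <- scores > threshold
  pos <- labels == 1L
  c(sens = if (any(pos)) sum(pred & pos) / sum(pos) else NaN,
    spec = if (any(!pos)) sum(!pred & !pos) / sum(!pos) else NaN)
}

#' Highest sensitivity at a specificity floor
#'
#' Returns the largest sensitivity achievable while keeping specificity at
#' least `target_spec`, together with the threshold that achieves it.
#' Sensitivity decreases and specificity increases with the threshold, so
#' the answer is the smallest candidate threshold whose specificity reaches
#' the target; the threshold `max(scores)` (all-negative, specificity 1,
#' sensitivity 0) is always available as a fallback.
#'
#' @param scores,labels As in [roc_curve()].
#' @param target_spec Specificity floor (default 0.9).
#' @return List with `sensitivity`, `specificity` and `threshold`.
#' @export
sensitivity_at_specificity <- function(scores, labels, target_spec = 0.9) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% 0:1), sum(labels == 0L) > 0L,
            sum(labels == 1L) > 0L)
  for (t in .candidate_thresholds(scores)) {
    ss <- .sens_spec_at(scores, labels, t)
    if (ss["spec"] >= target_spec)
      return(list(sensitivity = unname(ss["sens"]),
                  specificity = unname(ss["spec"]), threshold = t))
  }
  list(sensitivity = 0, specificity = 1, threshold = max(scores))
}

#' Youden-index threshold
#'
#' The threshold maximizing the Youden index J = sensitivity + specificity
#' - 1 over the candidate thresholds (midpoints of adjacent distinct scores
#' plus the extremes); ties go to the lower threshold. The maximal J is
#' attached as attribute `"J"`.
#'
#' @param scores,labels As in [roc_curve()].
#' @return The selected threshold (numeric scalar, attribute `J`).
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% 0:1))
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L)
    stop("Youden threshold needs both classes present", call. = FALSE)
  cand <- .candidate_thresholds(scores)
  J <- vapply(cand, function(t) {
    ss <- .sens_spec_at(scores, labels, t)
    unname(ss["sens"] + ss["spec"] - 1)
  }, numeric(1))
  best <- which.max(J)  # candidates ascend, so ties pick the lower threshold
  structure(cand[best], J = J[best])
}

#' Accuracy, sensitivity and specificity at a threshold
#'
#' Predictions are positive when the score strictly exceeds the threshold
#' (a score exactly at the threshold is called negative). Sensitivity is the
#' true-positive rate and specificity the true-negative rate; either is
#' `NaN` when the corresponding class is absent.
#'
#' @param scores,labels Scores and binary labels.
#' @param threshold Decision threshold (default 0.5, the model's native
#'   operating point).
#' @return Object of class `"eval_metrics"`: list with `accuracy`,
#'   `sensitivity`, `specificity`, `threshold_used`.
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  pred <- as.integer(scores > threshold)
  ss <- .sens_spec_at(scores, labels, threshold)
  structure(list(accuracy = mean(pred == labels),
                 sensitivity = unname(ss["sens"]),
                 specificity = unname(ss["spec"]),
                 threshold_used = threshold),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.3f | sensitivity %.3f | specificity %.3f (threshold %.3g)\n",
              x$accuracy, x$sensitivity, x$specificity, x$threshold_used))
  invisible(x)
}

.stratified_folds <- function(y, folds) {
  if (any(table(y) < folds))
    stop(sprintf("each class needs at least %d samples for %d-fold stratification",
                 folds, folds), call. = FALSE)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    ix <- sample(which(y == cls))
    fold[ix] <- rep_len(seq_len(folds), length(ix))
  }
  fold
}

#' Cross-validate a repertoire classifier
#'
#' Repeated stratified k-fold cross-validation following the evaluation
#' protocol of the model: in the plain scheme each rotation uses `folds - 2`
#' folds for training, one for validation (early stopping and best-of-n
#' selection) and one for testing; in the nested scheme an inner loop over
#' the non-test folds performs model selection (the candidate with the
#' highest inner-validation AUC is kept) and the outer fold gives the
#' unbiased test estimate. Five folds repeated 10 times yields 50 test
#' evaluations; the aggregate reports mean and 95% confidence interval
#' (mean +/- 1.96 SE) per metric.
#'
#' @param x List of labeled [repertoire()] objects.
#' @param labels Optional labels overriding those in `x`.
#' @param folds Number of folds (default 5).
#' @param repeats Number of repeats with reseeded fold assignment
#'   (default 10).
#' @param nested Use the nested scheme? Default `FALSE`.
#' @param seed Base seed; repeat `r` uses `seed + r - 1` for fold assignment
#'   and model training.
#' @param threshold Classification threshold for accuracy/sensitivity/
#'   specificity (default 0.5, the model's fixed operating point).
#' @param fit_fun Fitting function with signature `(x, labels, val,
#'   val_labels, seed, ...)` returning an object whose `predict(object,
#'   newdata)` yields numeric bag scores. Defaults to a wrapper around
#'   [tcrmil()].
#' @param ... Passed on to `fit_fun` (e.g. `epochs`, `k`, `n_runs`).
#' @return Object of class `"tcrmil_cv"`: list with `results` (one row per
#'   test evaluation: repeat, fold, auc, accuracy, sensitivity,
#'   specificity), `aggregate` (mean and 95% CI per metric), and
#'   `predictions` (pooled out-of-fold scores with labels).
#' @export
cross_validate <- function(x, labels = NULL, folds = 5L, repeats = 10L,
                           nested = FALSE, seed = 1L, threshold = 0.5,
                           fit_fun = NULL, ...) {
  stopifnot(folds >= 2L, repeats >= 1L)
  if (is.null(labels)) labels <- .bag_labels(x)
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("all samples need labels", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("cohort contains a single class", call. = FALSE)
  if (is.null(fit_fun)) {
    fit_fun <- function(x, labels, val, val_labels, seed, ...) {
      vv <- lapply(seq_along(val), function(i) {
        r <- val[[i]]; r$label <- val_labels[i]; r
      })
      tcrmil(x, labels = labels, val = vv, seed = seed, ...)
    }
  }
  rows <- list()
  preds <- list()
  for (r in seq_len(repeats)) {
    rep_seed <- seed + r - 1L
    set.seed(rep_seed)
    fold <- .stratified_folds(labels, folds)
    for (f in seq_len(folds)) {
      test_ix <- which(fold == f)
      if (nested) {
        inner <- setdiff(seq_len(folds), f)
        cands <- lapply(inner, function(g) {
          tr_ix <- which(!(fold %in% c(f, g)))
          va_ix <- which(fold == g)
          m <- fit_fun(x[tr_ix], labels[tr_ix], x[va_ix], labels[va_ix],
                       seed = rep_seed, ...)
          va <- if (!is.null(m$val_auc) && !is.na(m$val_auc)) m$val_auc
                else roc_auc(as.numeric(predict(m, x[va_ix])), labels[va_ix])$auc
          list(model = m, val_auc = va, seed = g)
        })
        model <- select_best_of_n(cands)$model
      } else {
        g <- if (f == folds) 1L else f + 1L  # rotate the validation fold
        tr_ix <- which(!(fold %in% c(f, g)))
        va_ix <- which(fold == g)
        model <- fit_fun(x[tr_ix], labels[tr_ix], x[va_ix], labels[va_ix],
                         seed = rep_seed, ...)
      }
      sc <- as.numeric(predict(model, x[test_ix]))
      y_te <- labels[test_ix]
      auc <- if (length(unique(y_te)) == 2L) roc_auc(sc, y_te)$auc else NA_real_
      cm <- confusion_metrics(sc, y_te, threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, fold = f, auc = auc, accuracy = cm$accuracy,
        sensitivity = cm$sensitivity, specificity = cm$specificity,
        n_test = length(test_ix))
      preds[[length(preds) + 1L]] <- data.frame(
        rep = r, fold = f, index = test_ix, score = sc, label = y_te)
    }
  }
  results <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(c("auc", "accuracy", "sensitivity",
                                 "specificity"), function(m) {
    v <- results[[m]]; v <- v[!is.na(v)]
    se <- stats::sd(v) / sqrt(length(v))
    data.frame(metric = m, mean = mean(v), ci_lo = mean(v) - 1.96 * se,
               ci_hi = mean(v) + 1.96 * se, n = length(v))
  }))
  structure(list(results = results, aggregate = agg,
                 predictions = do.call(rbind, preds),
                 folds = folds, repeats = repeats, nested = nested),
            class = "tcrmil_cv")
}

#' @export
print.tcrmil_cv <- function(x, ...) {
  cat(sprintf("%s %d-fold cross-validation, %d repeat(s) (%d evaluations)\n",
              if (x$nested) "Nested" else "Plain", x$folds, x$repeats,
              nrow(x$results)))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-12s %.3f (95%% CI %.3f-%.3f)\n", agg$metric[i],
                agg$mean[i], agg$ci_lo[i], agg$ci_hi[i]))
  invisible(x)
}
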