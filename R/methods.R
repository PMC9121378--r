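# S3 methods for fitted "tcrmil" models.

#' Predict repertoire cancer scores
#'
#' Applies the fitted model to new repertoires: quality filtering (when the
#' model was fitted with `qc = TRUE`), reference-set removal, top-k
#' selection, encoding and the deterministic forward pass (dropout off).
#'
#' @param object A fitted `"tcrmil"`.
#' @param newdata A [repertoire()] or list of repertoires; defaults to
#'   refusing silently absent data.
#' @param type `"response"` (bag cancer scores, default), `"class"` (0/1 at
#'   the strict 0.5 threshold) or `"tcr"` (list of per-sequence scores, one
#'   vector per repertoire, named by CDR3).
#' @param ... Unused.
#' @return Named numeric vector (or list for `type = "tcr"`).
#' @export
predict.tcrmil <- function(object, newdata,
                           type = c("response", "class", "tcr"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "repertoire")) newdata <- list(newdata)
  cfg <- object$config
  prep <- .preprocess_bags(newdata, cfg$k, object$reference,
                           qc = isTRUE(cfg$qc) || is.null(cfg$qc))
  ids <- vapply(prep, `[[`, character(1), "sample_id")
  dat <- .encode_bags(.bag_cdr3(prep), object$encoding, cfg$l_max,
                      object$bank$entries$h, cfg$k)
  cc <- .forward(object$par, dat, cfg$pooling, cfg$mask_padding)
  if (type == "tcr") {
    out <- split(stats::setNames(cc$s, unlist(.bag_cdr3(prep))), dat$seq_bag)
    names(out) <- ids[as.integer(names(out))]
    return(out)
  }
  scores <- stats::setNames(cc$Yhat, ids)
  if (type == "class") as.integer(scores > 0.5) else scores
}

#' @export
print.tcrmil <- function(x, ...) {
  cat("Multi-instance TCR repertoire classifier\n")
  cat(sprintf("  filters: %d over heights %s (d = %d, encoding '%s')\n",
              x$bank$n_total,
              paste(x$bank$entries$h, collapse = ","),
              x$bank$d, x$encoding$name))
  cat(sprintf("  bag size k = %d, pooling = %s, masked padding = %s\n",
              x$config$k, x$config$pooling, x$config$mask_padding))
  if (!is.null(x$val_auc) && !is.na(x$val_auc))
    cat(sprintf("  validation AUC of selected run: %.3f\n", x$val_auc))
  invisible(x)
}

#' Summarize a fitted repertoire classifier
#'
#' @param object A fitted `"tcrmil"`.
#' @param ... Unused.
#' @return Object of class `"summary.tcrmil"` with the model layout, per-run
#'   validation AUCs, training-set confusion metrics at the 0.5 threshold
#'   and the rank-weight profile of the bag classifier.
#' @export
summary.tcrmil <- function(object, ...) {
  train_metrics <- if (!is.null(object$fitted.values) &&
                       !is.null(object$labels) && !anyNA(object$labels)) {
    confusion_metrics(object$fitted.values, object$labels, 0.5)
  }
  structure(list(
    bank = object$bank,
    config = object$config,
    encoding_name = object$encoding$name,
    runs = object$runs,
    val_auc = object$val_auc,
    n_epochs_run = if (!is.null(object$history)) max(object$history$epoch),
    train_metrics = train_metrics,
    rank_weights = object$par$WLp
  ), class = "summary.tcrmil")
}

#' @export
print.summary.tcrmil <- function(x, ...) {
  cat("Multi-instance TCR repertoire classifier\n")
  print(x$bank)
  cat(sprintf("  k = %d, pooling = %s, dropout = %.0f%%, lr = %g\n",
              x$config$k, x$config$pooling, 100 * x$config$dropout,
              x$config$lr))
  if (!is.null(x$n_epochs_run))
    cat(sprintf("  selected run trained for %d epochs\n", x$n_epochs_run))
  if (!is.null(x$runs) && nrow(x$runs) > 0) {
    cat("  per-run validation AUC:",
        paste(format(x$runs$val_auc, digits = 3), collapse = ", "), "\n")
  }
  if (!is.null(x$train_metrics)) {
    cat("  training-set metrics at threshold 0.5:\n    ")
    print(x$train_metrics)
  }
  if (!is.null(x$rank_weights)) {
    w <- x$rank_weights
    cat(sprintf("  bag rank weights: mean %.3f, range [%.3f, %.3f]\n",
                mean(w), min(w), max(w)))
  }
  invisible(x)
}

#' Extract model coefficients
#'
#' @param object A fitted `"tcrmil"`.
#' @param ... Unused.
#' @return List with `W_L`/`b_L` (per-TCR classifier over the pooled
#'   features), `W_Lp`/`b_Lp` (bag classifier over the k rank-ordered TCR
#'   scores) and `filters` (list of `h x d` weight matrices with biases).
#' @export
coef.tcrmil <- function(object, ...) {
  list(W_L = object$params$W_L, b_L = object$params$b_L,
       W_Lp = object$params$W_Lp, b_Lp = object$params$b_Lp,
       filters = lapply(object$params$filters,
                        function(f) list(h = f$h, W = f$W, b = f$b)))
}

#' Residuals of a fitted repertoire classifier
#'
#' Response residuals `label - fitted cancer score` on the training cohort.
#'
#' @param object A fitted `"tcrmil"`.
#' @param ... Unused.
#' @export
residuals.tcrmil <- function(object, ...) {
  if (is.null(object$fitted.values) || is.null(object$labels))
    stop("model carries no training fits", call. = FALSE)
  object$labels - object$fitted.values
}

#' Plot training history and training-set ROC
#'
#' `which = 1` draws the per-epoch training/validation loss curves of the
#' selected run; `which = 2` the ROC curve of the fitted scores on the
#' training cohort.
#'
#' @param x A fitted `"tcrmil"`.
#' @param which Subset of `1:2`.
#' @param ... Passed to the base plotting calls.
#' @export
plot.tcrmil <- function(x, which = 1:2, ...) {
  if (1 %in% which && !is.null(x$history)) {
    h <- x$history
    ylim <- range(c(h$train_loss, h$val_loss), na.rm = TRUE)
    graphics::plot(h$epoch, h$train_loss, type = "l", ylim = ylim,
                   xlab = "epoch", ylab = "cross-entropy loss",
                   main = "Training history", ...)
    if (!all(is.na(h$val_loss)))
      graphics::lines(h$epoch, h$val_loss, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2,
                     bty = "n")
  }
  if (2 %in% which && !is.null(x$fitted.values) && !anyNA(x$labels)) {
    roc <- roc_auc(x$fitted.values, x$labels)
    graphics::plot(roc$points$fpr, roc$points$tpr, type = "l",
                   xlab = "false-positive rate", ylab = "true-positive rate",
                   main = sprintf("Training ROC (AUC = %.3f)", roc$auc), ...)
    graphics::abline(0, 1, lty = 3)
  }
  invisible(x)
}

#' Simulate bag labels from the fitted probabilities
#'
#' Draws Bernoulli labels for the training cohort from the fitted cancer
#' scores — a parametric-bootstrap building block.
#'
#' @param object A fitted `"tcrmil"`.
#' @param nsim Number of simulated label vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return data.frame with `nsim` columns of 0/1 labels, one row per
#'   training sample.
#' @export
simulate.tcrmil <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$fitted.values))
    stop("model carries no fitted values", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- object$fitted.values
  out <- as.data.frame(matrix(
    stats::rbinom(length(p) * nsim, 1L, rep(p, nsim)),
    ncol = nsim, dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
  attr(out, "seed") <- seed
  out
}
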