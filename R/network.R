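# The per-TCR convolutional scorer and the MIL bag classifier.
#
# Per TCR: an l x d input matrix is scanned by a bank of h x d filters
# (stride 1, ReLU), each feature map is reduced to one number by 1-max
# pooling (best-matching window = the candidate motif), the pooled features
# are concatenated and a one-layer linear classifier with a sigmoid turns
# them into the probability that the TCR is cancer-associated. Per bag: the
# k per-TCR scores, ordered by clonal-frequency rank, feed a second
# one-layer linear classifier whose sigmoid output is the repertoire cancer
# score. These functions are the readable per-sequence implementation; the
# trainer uses an equivalent batched path (see fit.R) that is tested against
# this one.

#' Create a convolution filter
#'
#' @param W `h x d` numeric weight matrix.
#' @param b Scalar bias.
#' @return Object of class `"conv_filter"` with fields `h`, `d`, `W`, `b`.
#' @export
conv_filter <- function(W, b = 0) {
  W <- as.matrix(W)
  stopifnot(is.numeric(W), all(is.finite(W)), is.finite(b), nrow(W) >= 1L)
  structure(list(h = nrow(W), d = ncol(W), W = W, b = as.numeric(b)),
            class = "conv_filter")
}

#' Convolve a TCR matrix with one filter
#'
#' Slides the `h x d` filter over the rows of the (possibly padded) input
#' with stride 1 and no spatial padding, applying ReLU:
#' `values[a] = max(0, sum(W * M[a:(a+h-1), ]) + b)`. Windows that overlap
#' zero-padding rows are flagged `valid = FALSE` so pooling can exclude
#' them.
#'
#' @param M A `"tcr_matrix"` from [encode_sequence()].
#' @param f A [conv_filter()].
#' @return Object of class `"feature_map"`: list with `values` (length
#'   `nrow - h + 1`) and logical `valid`.
#' @export
convolve <- function(M, f) {
  stopifnot(inherits(M, "tcr_matrix"), inherits(f, "conv_filter"))
  if (M$true_length < f$h)
    stop(sprintf("sequence length %d is shorter than filter height %d",
                 M$true_length, f$h), call. = FALSE)
  if (ncol(M$values) != f$d)
    stop("filter and input feature dimensions differ", call. = FALSE)
  n_win <- nrow(M$values) - f$h + 1L
  vals <- numeric(n_win)
  for (a in seq_len(n_win)) {
    vals[a] <- sum(f$W * M$values[a:(a + f$h - 1L), , drop = FALSE]) + f$b
  }
  vals <- pmax(vals, 0)
  structure(list(values = vals,
                 valid = seq_len(n_win) + f$h - 1L <= M$true_length),
            class = "feature_map")
}

#' Pool a feature map to a single value
#'
#' Three reductions of a convolution feature map to one number: the
#' element-wise maximum (1-max pooling, the default throughout the model:
#' the best-matching window is taken as the candidate motif), the
#' element-wise average, and log-sum-exp, `log(mean(exp(o)))`. With
#' `mask_padding = TRUE` only windows that do not overlap padding
#' participate, which enforces the property that padding never contributes
#' a pooled feature.
#'
#' @param map A `"feature_map"` from [convolve()].
#' @param mode `"max"`, `"avg"` or `"lse"`.
#' @param mask_padding Exclude padding-overlapping windows? Default `TRUE`.
#' @return A single numeric value.
#' @export
pool <- function(map, mode = c("max", "avg", "lse"), mask_padding = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "feature_map"))
  v <- if (mask_padding) map$values[map$valid] else map$values
  if (!length(v)) stop("no eligible windows to pool", call. = FALSE)
  switch(mode,
    max = max(v),
    avg = mean(v),
    lse = log(mean(exp(v)))
  )
}

#' Initialize the per-TCR scorer parameters
#'
#' Creates one [conv_filter()] per slot of the filter-bank specification and
#' the linear classifier weights. All weight matrices use Xavier/Glorot
#' uniform initialization (limit `sqrt(6 / (fan_in + fan_out))`), which
#' mitigates dead-ReLU units; biases start at zero.
#'
#' @param bank A `"filter_bank"` from [design_filter_bank()].
#' @param k Bag size; when non-`NULL` the returned object also carries the
#'   bag-classifier parameters `W_Lp` (length `k`) and `b_Lp`.
#' @param seed Optional integer seed for reproducible initialization.
#' @return Object of class `"tcr_scorer_params"`: list with `bank`,
#'   `filters` (list of `conv_filter`, ascending height then slot), `W_L`,
#'   `b_L`, and optionally `W_Lp`, `b_Lp`, `k`.
#' @export
init_params <- function(bank, k = NULL, seed = NULL) {
  stopifnot(inherits(bank, "filter_bank"))
  if (!is.null(seed)) set.seed(seed)
  xavier <- function(fan_in, fan_out, n) {
    lim <- sqrt(6 / (fan_in + fan_out))
    stats::runif(n, -lim, lim)
  }
  filters <- list()
  for (i in seq_len(nrow(bank$entries))) {
    h <- bank$entries$h[i]
    for (s in seq_len(bank$entries$n_filters[i])) {
      W <- matrix(xavier(h * bank$d, 1L, h * bank$d), nrow = h)
      filters[[length(filters) + 1L]] <- conv_filter(W, 0)
    }
  }
  nf <- length(filters)
  out <- list(bank = bank, filters = filters,
              W_L = xavier(nf, 1L, nf), b_L = 0)
  if (!is.null(k)) {
    out$k <- as.integer(k)
    out$W_Lp <- xavier(k, 1L, k)
    out$b_Lp <- 0
  }
  structure(out, class = "tcr_scorer_params")
}

#' Pooled feature vector of one TCR
#'
#' Applies every filter of the bank to the input and pools each feature map,
#' in fixed bank order (ascending height, then slot), yielding the per-TCR
#' feature vector (length 14 for the default bank).
#'
#' @param M A `"tcr_matrix"`.
#' @param params A `"tcr_scorer_params"` from [init_params()].
#' @param mode,mask_padding Passed to [pool()].
#' @return Numeric vector, one pooled feature per filter.
#' @export
feature_vector <- function(M, params, mode = "max", mask_padding = TRUE) {
  stopifnot(inherits(params, "tcr_scorer_params"))
  vapply(params$filters,
         function(f) pool(convolve(M, f), mode, mask_padding),
         numeric(1))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Score one TCR
#'
#' The probability that the TCR is cancer-associated: a one-layer linear
#' classifier over the pooled feature vector followed by a sigmoid,
#' `sigmoid(W_L . p + b_L)`. A TCR is called cancer-associated when the
#' score exceeds 0.5 (strictly).
#'
#' @param p Feature vector from [feature_vector()].
#' @param params A `"tcr_scorer_params"`.
#' @return Score in (0, 1).
#' @export
tcr_score <- function(p, params) {
  stopifnot(inherits(params, "tcr_scorer_params"))
  if (length(p) != length(params$W_L))
    stop("feature vector length does not match classifier weights",
         call. = FALSE)
  sigmoid(sum(params$W_L * p) + params$b_L)
}

#' Binary cross-entropy loss
#'
#' The negative Bernoulli log-likelihood `-(y log yhat + (1-y) log(1-yhat))`,
#' with the prediction clamped to `[1e-12, 1 - 1e-12]` before the logarithm.
#' The same loss applies at the TCR level ([tcr_loss()]) and at the bag
#' level ([mil_loss()]).
#'
#' @param y_hat Predicted probability (vector allowed).
#' @param y True binary label(s).
#' @return Non-negative loss value(s).
#' @export
tcr_loss <- function(y_hat, y) {
  y_hat <- pmin(pmax(y_hat, 1e-12), 1 - 1e-12)
  -(y * log(y_hat) + (1 - y) * log(1 - y_hat))
}

#' @rdname tcr_loss
#' @export
mil_loss <- tcr_loss

#' Aggregate k per-TCR scores into a bag prediction
#'
#' The learned aggregator: `Y_hat = sigmoid(W_Lp . scores + b_Lp)`, where
#' the score vector is ordered by clonal-frequency rank so each weight of
#' `W_Lp` attaches to an abundance rank. Repertoires with fewer than `k`
#' surviving TCRs have the missing slots filled with score 0 ("no
#' evidence") before aggregation.
#'
#' @param scores Numeric vector of length `k` of per-TCR scores.
#' @param params A `"tcr_scorer_params"` carrying `W_Lp`/`b_Lp` (see
#'   [init_params()] with `k`).
#' @return Object of class `"bag_prediction"`: list with `Y_hat`,
#'   `tcr_scores` and `label_pred` (`Y_hat > 0.5`).
#' @export
bag_score <- function(scores, params) {
  stopifnot(inherits(params, "tcr_scorer_params"))
  if (is.null(params$W_Lp)) stop("params carry no bag classifier", call. = FALSE)
  if (length(scores) != length(params$W_Lp))
    stop(sprintf("expected %d scores, got %d", length(params$W_Lp),
                 length(scores)), call. = FALSE)
  Y_hat <- sigmoid(sum(params$W_Lp * scores) + params$b_Lp)
  structure(list(Y_hat = Y_hat, tcr_scores = scores,
                 label_pred = as.integer(Y_hat > 0.5)),
            class = "bag_prediction")
}

#' @export
print.bag_prediction <- function(x, ...) {
  cat(sprintf("Bag prediction: cancer score %.4f -> %s\n", x$Y_hat,
              if (x$label_pred == 1L) "cancer" else "non-cancer"))
  invisible(x)
}

#' Baseline (unlearned) bag aggregators
#'
#' The two aggregation rules the learned classifier is compared against:
#' the mean of all TCR scores (the repertoire cancer score used by
#' average-based predictors) and the maximum (the standard MIL assumption —
#' one positive instance makes the bag positive). Both are permutation
#' invariant, unlike the learned aggregator.
#'
#' @param scores Non-empty numeric vector of per-TCR scores.
#' @param mode `"mean"` or `"max"`.
#' @return A single numeric score.
#' @export
baseline_aggregate <- function(scores, mode = c("mean", "max")) {
  mode <- match.arg(mode)
  if (!length(scores)) stop("no scores to aggregate", call. = FALSE)
  switch(mode, mean = mean(scores), max = max(scores))
}

#' Forward pass for one repertoire
#'
#' Encodes the top `k` clonotypes (the repertoire is expected to be
#' quality-filtered, reference-removed and rank-ordered), scores each with
#' the shared convolutional scorer, zero-fills missing slots and aggregates
#' with the learned bag classifier. Dropout is inference-off: given fixed
#' parameters this function is deterministic.
#'
#' @param rep A preprocessed [repertoire()].
#' @param params A `"tcr_scorer_params"` with bag classifier.
#' @param enc Encoding (anything accepted by [load_encoding()]).
#' @param l_max Padded length.
#' @param mode,mask_padding Pooling configuration.
#' @return A `"bag_prediction"`.
#' @export
forward_bag <- function(rep, params, enc = load_encoding("atchley"),
                        l_max = 24L, mode = "max", mask_padding = TRUE) {
  stopifnot(inherits(rep, "repertoire"))
  enc <- load_encoding(enc)
  k <- length(params$W_Lp)
  if (is.null(k) || k == 0L) stop("params carry no bag classifier", call. = FALSE)
  cdr3 <- utils::head(rep$clonotypes$cdr3, k)
  if (!length(cdr3)) stop("empty repertoire after preprocessing", call. = FALSE)
  scores <- numeric(k)
  for (i in seq_along(cdr3)) {
    M <- encode_sequence(cdr3[i], enc, l_max)
    scores[i] <- tcr_score(feature_vector(M, params, mode, mask_padding), params)
  }
  bag_score(scores, params)
}
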