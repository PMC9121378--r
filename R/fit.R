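# Training engine: a vectorised implementation of the CNN + MIL forward and
# backward passes, equivalent to the per-sequence reference functions in
# network.R (the equivalence is tested). Parameters are held per filter
# height as (h*d) x n_filters weight matrices; a window of the input is
# flattened position-major so column (t-1)*d + j of a weight matrix is
# filter entry (row t, feature j).

# ---- parameter container ---------------------------------------------------

.params_to_par <- function(params) {
  bank <- params$bank
  heights <- bank$entries$h
  d <- bank$d
  Wf <- list(); bf <- list()
  pos <- 1L
  for (i in seq_along(heights)) {
    n_h <- bank$entries$n_filters[i]
    Wm <- matrix(0, heights[i] * d, n_h)
    bv <- numeric(n_h)
    for (s in seq_len(n_h)) {
      f <- params$filters[[pos]]
      Wm[, s] <- as.vector(t(f$W))  # position-major
      bv[s] <- f$b
      pos <- pos + 1L
    }
    Wf[[i]] <- Wm; bf[[i]] <- bv
  }
  list(Wf = Wf, bf = bf, WL = params$W_L, bL = params$b_L,
       WLp = params$W_Lp, bLp = params$b_Lp,
       entries = bank$entries, d = d, k = params$k)
}

.par_to_params <- function(par, bank) {
  filters <- list()
  for (i in seq_len(nrow(par$entries))) {
    h <- par$entries$h[i]
    for (s in seq_len(par$entries$n_filters[i])) {
      W <- matrix(par$Wf[[i]][, s], nrow = h, byrow = TRUE)
      filters[[length(filters) + 1L]] <- conv_filter(W, par$bf[[i]][s])
    }
  }
  out <- list(bank = bank, filters = filters, W_L = par$WL, b_L = par$bL)
  if (!is.null(par$WLp)) {
    out$k <- par$k; out$W_Lp <- par$WLp; out$b_Lp <- par$bLp
  }
  structure(out, class = "tcr_scorer_params")
}

.flatten_par <- function(par) {
  c(unlist(par$Wf, use.names = FALSE), unlist(par$bf, use.names = FALSE),
    par$WL, par$bL, par$WLp, par$bLp)
}

.unflatten_par <- function(vec, tmpl) {
  out <- tmpl
  pos <- 1L
  for (i in seq_along(tmpl$Wf)) {
    n <- length(tmpl$Wf[[i]])
    out$Wf[[i]] <- matrix(vec[pos:(pos + n - 1L)], nrow = nrow(tmpl$Wf[[i]]))
    pos <- pos + n
  }
  for (i in seq_along(tmpl$bf)) {
    n <- length(tmpl$bf[[i]])
    out$bf[[i]] <- vec[pos:(pos + n - 1L)]; pos <- pos + n
  }
  n <- length(tmpl$WL); out$WL <- vec[pos:(pos + n - 1L)]; pos <- pos + n
  out$bL <- vec[pos]; pos <- pos + 1L
  if (!is.null(tmpl$WLp)) {
    n <- length(tmpl$WLp); out$WLp <- vec[pos:(pos + n - 1L)]; pos <- pos + n
    out$bLp <- vec[pos]
  }
  out
}

# ---- bag encoding ----------------------------------------------------------

# bag_seqs: list of character vectors (rank-ordered, length <= k each)
.encode_bags <- function(bag_seqs, enc, l_max, heights, k) {
  counts <- lengths(bag_seqs)
  if (any(counts == 0L)) stop("empty repertoire after preprocessing", call. = FALSE)
  if (any(counts > k)) stop("a bag holds more than k sequences", call. = FALSE)
  n_bags <- length(bag_seqs)
  seqs <- unlist(bag_seqs, use.names = FALSE)
  N <- length(seqs)
  L <- nchar(seqs)
  if (any(L > l_max)) stop("sequence longer than l_max", call. = FALSE)
  d <- enc$d
  chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  if (!all(chars %in% AA_ALPHABET))
    stop("sequence contains letters outside the 20 standard amino acids",
         call. = FALSE)
  Emat <- matrix(0, N * l_max, d)
  rowidx <- rep.int((seq_len(N) - 1L) * l_max, times = L) +
    unlist(lapply(L, seq_len), use.names = FALSE)
  Emat[rowidx, ] <- enc$M[chars, , drop = FALSE]

  X <- vector("list", length(heights))
  valid <- vector("list", length(heights))
  nv <- vector("list", length(heights))
  Wd <- integer(length(heights))
  for (i in seq_along(heights)) {
    h <- heights[i]
    W <- l_max - h + 1L
    Wd[i] <- W
    base <- rep((seq_len(N) - 1L) * l_max, each = W)
    avec <- rep.int(seq_len(W), times = N)
    Xi <- matrix(0, N * W, h * d)
    for (t in seq_len(h)) {
      Xi[, ((t - 1L) * d + 1L):(t * d)] <- Emat[base + avec + (t - 1L), ,
                                                drop = FALSE]
    }
    X[[i]] <- Xi
    valid[[i]] <- (avec + h - 1L) <= L[rep(seq_len(N), each = W)]
    nv[[i]] <- pmax(L - h + 1L, 0L)
  }
  list(N = N, n_bags = n_bags, counts = counts, k = as.integer(k),
       seq_bag = rep(seq_len(n_bags), counts),
       seq_slot = unlist(lapply(counts, seq_len), use.names = FALSE),
       X = X, valid = valid, nv = nv, W = Wd, heights = heights,
       d = d, l_max = l_max, L = L)
}

.subset_dat <- function(dat, bags) {
  sel <- dat$seq_bag %in% bags
  selseq <- which(sel)
  out <- dat
  out$n_bags <- length(bags)
  out$counts <- dat$counts[bags]
  out$seq_bag <- match(dat$seq_bag[sel], bags)
  out$seq_slot <- dat$seq_slot[sel]
  out$N <- length(selseq)
  out$L <- dat$L[selseq]
  for (i in seq_along(dat$heights)) {
    W <- dat$W[i]
    rows <- rep((selseq - 1L) * W, each = W) + rep.int(seq_len(W), length(selseq))
    out$X[[i]] <- dat$X[[i]][rows, , drop = FALSE]
    out$valid[[i]] <- dat$valid[[i]][rows]
    out$nv[[i]] <- dat$nv[[i]][selseq]
  }
  out
}

# ---- forward / backward ----------------------------------------------------

# Pool every filter over every sequence. Returns the N x nf feature matrix
# plus the per-height caches backward needs.
.pool_forward <- function(par, dat, pooling, mask_padding) {
  N <- dat$N
  nf <- length(par$WL)
  feat <- matrix(0, N, nf)
  blocks <- vector("list", length(dat$heights))
  col0 <- 0L
  for (i in seq_along(dat$heights)) {
    n_h <- par$entries$n_filters[i]
    W <- dat$W[i]
    P <- dat$X[[i]] %*% par$Wf[[i]]
    P <- P + rep(par$bf[[i]], each = nrow(P))
    inv <- if (mask_padding) !dat$valid[[i]] else rep(FALSE, nrow(P))
    nvi <- if (mask_padding) dat$nv[[i]] else rep.int(W, N)
    cache <- list(n_h = n_h, W = W)
    if (pooling == "max") {
      Pm <- P
      if (any(inv)) Pm[inv, ] <- -Inf
      B <- matrix(aperm(array(Pm, c(W, N, n_h)), c(2L, 3L, 1L)), N * n_h, W)
      idx <- max.col(B, ties.method = "first")
      pre <- matrix(B[cbind(seq_len(N * n_h), idx)], N, n_h)
      pooled <- pmax(pre, 0)
      pooled[!is.finite(pre)] <- 0  # no eligible window
      cache$idx <- matrix(idx, N, n_h)
      cache$active <- is.finite(pre) & pre > 0
    } else if (pooling == "avg") {
      R <- pmax(P, 0)
      if (any(inv)) R[inv, ] <- 0
      sums <- colSums(array(R, c(W, N, n_h)))      # N x n_h
      pooled <- sums / nvi
      pooled[nvi == 0L, ] <- 0
      cache$gate <- (P > 0) & !inv
      cache$nvi <- nvi
    } else { # lse
      R <- pmax(P, 0)
      E <- exp(R)
      if (any(inv)) E[inv, ] <- 0
      s <- colSums(array(E, c(W, N, n_h)))         # N x n_h
      pooled <- log(s / nvi)
      pooled[nvi == 0L, ] <- 0
      cache$gate <- (P > 0) & !inv
      cache$E <- E
      cache$S <- s
      cache$nvi <- nvi
    }
    feat[, (col0 + 1L):(col0 + n_h)] <- pooled
    blocks[[i]] <- cache
    col0 <- col0 + n_h
  }
  list(feat = feat, blocks = blocks)
}

.forward <- function(par, dat, pooling = "max", mask_padding = TRUE,
                     training = FALSE, dropout = 0) {
  pf <- .pool_forward(par, dat, pooling, mask_padding)
  feat <- pf$feat
  if (training && dropout > 0) {
    Dm <- matrix(stats::runif(length(feat)) >= dropout, nrow(feat), ncol(feat))
    feat_d <- feat * Dm / (1 - dropout)
  } else {
    Dm <- NULL
    feat_d <- feat
  }
  slogit <- drop(feat_d %*% par$WL) + par$bL
  s <- sigmoid(slogit)
  out <- list(blocks = pf$blocks, feat = feat, Dm = Dm, feat_d = feat_d,
              s = s)
  if (!is.null(par$WLp)) {
    S <- matrix(0, dat$n_bags, par$k)
    S[cbind(dat$seq_bag, dat$seq_slot)] <- s
    if (training && dropout > 0) {
      D2 <- matrix(stats::runif(length(S)) >= dropout, nrow(S), ncol(S))
      Sd <- S * D2 / (1 - dropout)
    } else {
      D2 <- NULL
      Sd <- S
    }
    out$S <- S; out$D2 <- D2; out$Sd <- Sd
    out$Yhat <- sigmoid(drop(Sd %*% par$WLp) + par$bLp)
  }
  out
}

# Gradient of the mean cross-entropy bag loss w.r.t. all parameters.
.backward_mil <- function(par, dat, cache, y, dropout = 0) {
  n_bags <- dat$n_bags
  gY <- (cache$Yhat - y) / n_bags
  grad <- list(Wf = vector("list", length(par$Wf)),
               bf = vector("list", length(par$bf)),
               entries = par$entries, d = par$d, k = par$k)
  grad$WLp <- drop(crossprod(cache$Sd, gY))
  grad$bLp <- sum(gY)
  dSd <- outer(gY, par$WLp)
  dS <- if (!is.null(cache$D2)) dSd * cache$D2 / (1 - dropout) else dSd
  ds <- dS[cbind(dat$seq_bag, dat$seq_slot)]
  .backward_scorer(par, dat, cache, ds, dropout, grad)
}

# Gradient of the mean cross-entropy per-TCR loss (instance-level training).
.backward_tcr <- function(par, dat, cache, y, dropout = 0) {
  grad <- list(Wf = vector("list", length(par$Wf)),
               bf = vector("list", length(par$bf)),
               entries = par$entries, d = par$d, k = par$k)
  ds_logit <- (cache$s - y) / dat$N
  .backward_scorer(par, dat, cache, NULL, dropout, grad,
                   ds_logit = ds_logit)
}

# Shared tail: from d(loss)/d(score) back to filters. Either `ds` (gradient
# w.r.t. post-sigmoid scores) or `ds_logit` is supplied.
.backward_scorer <- function(par, dat, cache, ds, dropout, grad,
                             ds_logit = NULL) {
  if (is.null(ds_logit)) ds_logit <- ds * cache$s * (1 - cache$s)
  grad$WL <- drop(crossprod(cache$feat_d, ds_logit))
  grad$bL <- sum(ds_logit)
  dfeat <- outer(ds_logit, par$WL)
  if (!is.null(cache$Dm)) dfeat <- dfeat * cache$Dm / (1 - dropout)
  N <- dat$N
  col0 <- 0L
  for (i in seq_along(dat$heights)) {
    blk <- cache$blocks[[i]]
    n_h <- blk$n_h
    W <- blk$W
    g <- dfeat[, (col0 + 1L):(col0 + n_h), drop = FALSE]
    if (!is.null(blk$idx)) {              # max pooling
      g <- g * blk$active
      G <- matrix(0, N * W, n_h)
      nvec <- rep.int(seq_len(N), n_h)
      grow <- (nvec - 1L) * W + as.vector(blk$idx)
      jvec <- rep(seq_len(n_h), each = N)
      nz <- as.vector(g) != 0
      if (any(nz)) G[cbind(grow[nz], jvec[nz])] <- as.vector(g)[nz]
      grad$Wf[[i]] <- crossprod(dat$X[[i]], G)
      grad$bf[[i]] <- colSums(g)
    } else if (is.null(blk$E)) {          # avg pooling
      gb <- g / blk$nvi
      gb[blk$nvi == 0L, ] <- 0
      G <- gb[rep(seq_len(N), each = W), , drop = FALSE] * blk$gate
      grad$Wf[[i]] <- crossprod(dat$X[[i]], G)
      grad$bf[[i]] <- colSums(G)
    } else {                              # lse pooling
      wgt <- blk$E / blk$S[rep(seq_len(N), each = W), , drop = FALSE]
      G <- g[rep(seq_len(N), each = W), , drop = FALSE] * wgt * blk$gate
      grad$Wf[[i]] <- crossprod(dat$X[[i]], G)
      grad$bf[[i]] <- colSums(G)
    }
    col0 <- col0 + n_h
  }
  grad
}

.mean_loss <- function(y_hat, y) mean(tcr_loss(y_hat, y))

# ---- Adam ------------------------------------------------------------------

.adam_init <- function(theta) list(m = numeric(length(theta)),
                                   v = numeric(length(theta)), t = 0L)

.adam_step <- function(theta, g, st, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g * g
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = st)
}

# ---- training loop ---------------------------------------------------------

# level: "mil" (bag labels) or "tcr" (per-sequence labels; dat bags are
# singleton sequences and par has no bag classifier).
#
# Early stopping monitors validation AUC (the model-selection criterion)
# with validation loss as tiebreak, restoring the best checkpoint; without a
# validation set it monitors the training loss. During the first
# `warmup_epochs` of MIL training the bag classifier is frozen, so the
# scorer learns under the fixed mean aggregator before rank weights are
# allowed to move (see the methods vignette).
.train_loop <- function(par, dat, y, dat_val = NULL, y_val = NULL,
                        level = "mil", epochs = 700L, lr = 0.001,
                        dropout = 0.4, patience = 50L, batch_size = 512L,
                        pooling = "max", mask_padding = TRUE,
                        warmup_epochs = 0L, verbose = FALSE) {
  theta <- .flatten_par(par)
  st <- .adam_init(theta)
  n_par <- length(theta)
  n_head <- if (level == "mil") length(par$WLp) + 1L else 0L
  n_units <- if (level == "mil") dat$n_bags else dat$N
  full_batch <- n_units <= batch_size
  has_val <- !is.null(dat_val)
  best_auc <- -Inf; best_loss <- Inf; best_theta <- theta; wait <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), val_auc = numeric(0))
  for (ep in seq_len(epochs)) {
    if (full_batch) {
      batches <- list(seq_len(n_units))
    } else {
      ord <- sample.int(n_units)
      # batch membership is random; indices are sorted within each batch so
      # that subset predictions align with subset labels
      batches <- lapply(split(ord, ceiling(seq_along(ord) / batch_size)), sort)
    }
    tr_loss <- 0; n_seen <- 0L
    for (b in batches) {
      dat_b <- if (full_batch) dat else .subset_dat(dat, b)
      y_b <- y[b]
      par <- .unflatten_par(theta, par)
      cache <- .forward(par, dat_b, pooling, mask_padding,
                        training = TRUE, dropout = dropout)
      pred <- if (level == "mil") cache$Yhat else cache$s
      tr_loss <- tr_loss + .mean_loss(pred, y_b) * length(b)
      n_seen <- n_seen + length(b)
      grad <- if (level == "mil") .backward_mil(par, dat_b, cache, y_b, dropout)
              else .backward_tcr(par, dat_b, cache, y_b, dropout)
      gvec <- .flatten_par(grad)
      # warm-up freezes the rank weights only; the intercept keeps training
      # so the frozen aggregator stays a *calibrated* mean
      if (ep <= warmup_epochs && n_head > 0L)
        gvec[(n_par - n_head + 1L):(n_par - 1L)] <- 0
      upd <- .adam_step(theta, gvec, st, lr)
      theta <- upd$theta; st <- upd$state
    }
    tr_loss <- tr_loss / n_seen
    val_loss <- NA_real_; val_auc <- NA_real_
    if (has_val) {
      par <- .unflatten_par(theta, par)
      vc <- .forward(par, dat_val, pooling, mask_padding, training = FALSE)
      vpred <- if (level == "mil") vc$Yhat else vc$s
      val_loss <- .mean_loss(vpred, y_val)
      if (length(unique(y_val)) == 2L)
        val_auc <- roc_auc(vpred, y_val)$auc
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tr_loss,
                                   val_loss = val_loss, val_auc = val_auc))
    if (has_val && !is.na(val_auc)) {
      improved <- val_auc > best_auc + 1e-12 ||
        (val_auc >= best_auc - 1e-12 && val_loss < best_loss - 1e-12)
      if (improved) {
        best_auc <- max(best_auc, val_auc); best_loss <- val_loss
        best_theta <- theta; wait <- 0L
      } else wait <- wait + 1L
    } else {
      monitor <- if (has_val) val_loss else tr_loss
      if (monitor < best_loss - 1e-12) {
        best_loss <- monitor; best_theta <- theta; wait <- 0L
      } else wait <- wait + 1L
    }
    if (wait >= patience && ep > warmup_epochs) break
    if (verbose && ep %% 50L == 0L)
      message(sprintf("epoch %d: train %.4f val %.4f", ep, tr_loss,
                      if (has_val) val_loss else NA))
  }
  par <- .unflatten_par(best_theta, par)
  list(par = par, history = hist, best_loss = best_loss)
}

# ---- preprocessing shared by fit and predict --------------------------------

.preprocess_bags <- function(x, k, reference = NULL, qc = TRUE) {
  if (inherits(x, "repertoire")) x <- list(x)
  lapply(x, function(r) {
    stopifnot(inherits(r, "repertoire"))
    if (qc) r <- qc_filter(r)
    select_top_k(r, k, reference)
  })
}

.bag_cdr3 <- function(reps) lapply(reps, function(r) r$clonotypes$cdr3)

.bag_labels <- function(reps) vapply(reps, function(r) as.integer(r$label),
                                     integer(1))

# ---- the model-fitting front end -------------------------------------------

#' Fit a multi-instance TCR repertoire classifier
#'
#' Trains the full model end to end: each repertoire's top `k` clonotypes
#' are encoded as padded biochemical matrices, scored by a shared
#' convolutional scorer (multi-width filter bank, 1-max pooling, one-layer
#' linear classifier with sigmoid), and the `k` rank-ordered scores are
#' aggregated by a second one-layer linear classifier into the repertoire
#' cancer score. Both classifiers receive 40% dropout during training; the
#' whole model is trained jointly by Adam on the binary cross-entropy of the
#' bag labels, with early stopping on validation loss. The model is trained
#' `n_runs` times from independent seeded initializations and the run with
#' the highest validation AUC is kept.
#'
#' @param x List of labeled [repertoire()] objects (or use `labels`).
#' @param labels Optional numeric/integer vector of bag labels (1 = cancer);
#'   taken from the repertoires when `NULL`.
#' @param k Clonotypes per bag (default 100).
#' @param encoding Amino-acid encoding: `"atchley"`, `"kidera"`, a file path
#'   or an `"aa_encoding"` object.
#' @param l_max Padded sequence length (default 24).
#' @param bank Optional `"filter_bank"`; defaults to
#'   `design_filter_bank(contact_region_table(), d)`.
#' @param pooling Pooling mode: `"max"` (default), `"avg"` or `"lse"`.
#' @param mask_padding Exclude padding-overlapping windows from pooling
#'   (default `TRUE`).
#' @param reference `NULL` (no shared-sequence removal), a
#'   `"reference_set"`, or `TRUE` to build one from the training samples
#'   with [build_reference_set()].
#' @param reference_top_n `top_n` used when `reference = TRUE`.
#' @param qc Apply [qc_filter()] to each repertoire (default `TRUE`).
#' @param val Validation set for early stopping and model selection: a
#'   fraction in (0, 1) (stratified split of `x`, default 0.2), an integer
#'   vector of indices into `x`, or a list of labeled repertoires.
#' @param epochs,lr,dropout,patience,batch_size Training controls (defaults:
#'   700 epochs, learning rate 0.001, 40% dropout, early-stopping patience
#'   50, full-batch up to 512 bags then mini-batches).
#' @param warmup Fraction of `epochs` (in `[0, 1]`) during which the bag
#'   classifier is frozen at the calibrated mean aggregator (`W_Lp = 1/k`,
#'   `b_Lp = 0`) while the convolutional scorer trains under coherent
#'   bag-level gradients; after the warm-up the aggregator weights are
#'   released. Default 0.5. Set 0 to train everything from the first epoch.
#' @param aggregator_init `"mean"` (default; start at the calibrated mean
#'   aggregator) or `"xavier"` for symmetric random initialization of the
#'   bag classifier.
#' @param n_runs Number of independent training runs; the run with the
#'   highest validation AUC is kept, ties going to the lowest seed
#'   (default 5).
#' @param seed Integer seed; run `r` uses `seed + r - 1`.
#' @param verbose Print progress.
#' @return An object of class `"tcrmil"` with components `params` (the
#'   fitted `"tcr_scorer_params"`), `fitted.values` (bag scores on `x`),
#'   `labels`, `history` (per-epoch losses of the selected run), `val_auc`,
#'   `runs` (per-run seed and validation AUC), `config`, `encoding`,
#'   `reference` and `call`. Methods: `print`, `summary`, `coef`, `predict`,
#'   `plot`, `residuals`, `simulate`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(n_cancer = 8, n_control = 8,
#'                           seqs_per_sample = 20, seed = 1)
#' fit <- tcrmil(cohort$repertoires, k = 20, epochs = 40, n_runs = 1,
#'               seed = 1)
#' predict(fit, cohort$repertoires[1:2])
#' }
#' @export
tcrmil <- function(x, labels = NULL, k = 100L, encoding = "atchley",
                   l_max = 24L, bank = NULL,
                   pooling = c("max", "avg", "lse"), mask_padding = TRUE,
                   reference = NULL, reference_top_n = 20000L, qc = TRUE,
                   val = 0.2, epochs = 700L, lr = 0.001, dropout = 0.4,
                   patience = 50L, batch_size = 512L, warmup = 0.5,
                   aggregator_init = c("mean", "xavier"), n_runs = 5L,
                   seed = 1L, verbose = FALSE) {
  cl <- match.call()
  pooling <- match.arg(pooling)
  aggregator_init <- match.arg(aggregator_init)
  stopifnot(warmup >= 0, warmup <= 1)
  warmup_epochs <- as.integer(floor(warmup * epochs))
  seed <- as.integer(seed)
  enc <- load_encoding(encoding)
  if (is.null(bank)) bank <- design_filter_bank(contact_region_table(), d = enc$d)
  stopifnot(inherits(bank, "filter_bank"), bank$d == enc$d)
  if (inherits(x, "repertoire")) x <- list(x)
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(x))
    for (i in seq_along(x)) x[[i]]$label <- as.integer(labels[i])
  }
  y_all <- .bag_labels(x)
  if (anyNA(y_all)) stop("all training repertoires need labels", call. = FALSE)
  if (length(unique(y_all)) < 2L)
    stop("training set contains a single class", call. = FALSE)

  if (isTRUE(reference))
    reference <- build_reference_set(x, top_n = reference_top_n, qc = qc)
  if (!is.null(reference) && !isFALSE(reference))
    stopifnot(inherits(reference, "reference_set"))
  if (isFALSE(reference)) reference <- NULL

  # validation split (seeded, stratified) unless given explicitly
  set.seed(seed)
  if (is.list(val)) {
    x_val <- val
    x_tr <- x
  } else if (is.numeric(val) && length(val) == 1L && val > 0 && val < 1) {
    val_idx <- unlist(lapply(split(seq_along(x), y_all), function(ix) {
      n_val <- max(1L, round(length(ix) * val))
      sample(ix, n_val)
    }), use.names = FALSE)
    x_val <- x[val_idx]; x_tr <- x[-val_idx]
  } else if (is.numeric(val) && length(val) > 1L) {
    val_idx <- as.integer(val)
    x_val <- x[val_idx]; x_tr <- x[-val_idx]
  } else {
    x_val <- NULL; x_tr <- x
  }

  prep_tr <- .preprocess_bags(x_tr, k, reference, qc)
  dat_tr <- .encode_bags(.bag_cdr3(prep_tr), enc, l_max, bank$entries$h, k)
  y_tr <- .bag_labels(prep_tr)
  if (length(unique(y_tr)) < 2L)
    stop("training split contains a single class", call. = FALSE)
  dat_val <- NULL; y_val <- NULL
  if (!is.null(x_val)) {
    prep_val <- .preprocess_bags(x_val, k, reference, qc)
    dat_val <- .encode_bags(.bag_cdr3(prep_val), enc, l_max, bank$entries$h, k)
    y_val <- .bag_labels(prep_val)
  }

  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- seed + r - 1L
    params0 <- init_params(bank, k = k, seed = run_seed)
    par0 <- .params_to_par(params0)
    if (aggregator_init == "mean") {
      par0$WLp <- rep(1 / k, k)
      par0$bLp <- 0
    }
    res <- .train_loop(par0, dat_tr, y_tr, dat_val, y_val, level = "mil",
                       epochs = epochs, lr = lr, dropout = dropout,
                       patience = patience, batch_size = batch_size,
                       pooling = pooling, mask_padding = mask_padding,
                       warmup_epochs = warmup_epochs, verbose = verbose)
    va <- if (!is.null(dat_val)) {
      vc <- .forward(res$par, dat_val, pooling, mask_padding)
      if (length(unique(y_val)) == 2L) roc_auc(vc$Yhat, y_val)$auc else NA_real_
    } else NA_real_
    runs[[r]] <- list(par = res$par, history = res$history, val_auc = va,
                      seed = run_seed)
    if (verbose) message(sprintf("run %d (seed %d): val AUC %s", r, run_seed,
                                 format(va, digits = 3)))
  }
  best <- select_best_of_n(runs)

  config <- list(k = as.integer(k), l_max = as.integer(l_max),
                 pooling = pooling, mask_padding = mask_padding,
                 qc = qc, epochs = epochs, lr = lr, dropout = dropout,
                 patience = patience, batch_size = batch_size,
                 warmup = warmup, aggregator_init = aggregator_init,
                 n_runs = as.integer(n_runs), seed = as.integer(seed))
  obj <- structure(list(
    params = .par_to_params(best$par, bank),
    par = best$par,
    bank = bank,
    encoding = enc,
    reference = reference,
    config = config,
    history = best$history,
    val_auc = best$val_auc,
    runs = data.frame(seed = vapply(runs, `[[`, integer(1), "seed"),
                      val_auc = vapply(runs, `[[`, numeric(1), "val_auc")),
    labels = y_all,
    call = cl
  ), class = "tcrmil")
  obj$fitted.values <- unname(predict(obj, x))
  obj$sample_ids <- vapply(x, `[[`, character(1), "sample_id")
  obj
}

#' Select the best of several trained runs
#'
#' Returns the run with the highest validation AUC; ties are broken toward
#' the lowest seed. Accepts any list of objects carrying `val_auc` and
#' `seed` fields (e.g. the per-run results of [tcrmil()]).
#'
#' @param runs Non-empty list, each element with `val_auc` and `seed`.
#' @return The selected element.
#' @export
select_best_of_n <- function(runs) {
  stopifnot(length(runs) >= 1L)
  auc <- vapply(runs, function(r) {
    a <- r$val_auc
    if (is.null(a) || is.na(a)) -Inf else a
  }, numeric(1))
  seeds <- vapply(runs, function(r) as.numeric(r$seed), numeric(1))
  runs[[order(-auc, seeds)[1L]]]
}

# ---- instance-level trainer -------------------------------------------------

#' Train the per-TCR scorer on labeled sequences
#'
#' Instance-level training of the convolutional scorer alone: each CDR3
#' sequence carries its own binary label and the model minimizes the mean
#' per-TCR cross-entropy (no bag aggregation). Useful when candidate
#' cancer-associated sequences with labels are available.
#'
#' @param cdr3 Character vector of CDR3 sequences.
#' @param labels Binary labels, one per sequence.
#' @param encoding,l_max,bank,pooling,mask_padding As in [tcrmil()].
#' @param val Fraction for a stratified validation split (default 0.2), or
#'   `NULL` for none.
#' @param epochs Default 1000 for instance-level training.
#' @param lr,dropout,patience,batch_size,n_runs,seed,verbose As in
#'   [tcrmil()].
#' @return Object of class `"tcr_scorer_fit"` with `params`, `history`,
#'   `val_auc`, `runs`; `predict(fit, cdr3)` returns per-sequence scores.
#' @export
fit_tcr_scorer <- function(cdr3, labels, encoding = "atchley", l_max = 24L,
                           bank = NULL, pooling = "max", mask_padding = TRUE,
                           val = 0.2, epochs = 1000L, lr = 0.001,
                           dropout = 0.4, patience = 50L, batch_size = 512L,
                           n_runs = 5L, seed = 1L, verbose = FALSE) {
  seed <- as.integer(seed)
  enc <- load_encoding(encoding)
  if (is.null(bank)) bank <- design_filter_bank(contact_region_table(), d = enc$d)
  y <- as.integer(labels)
  stopifnot(length(cdr3) == length(y))
  if (length(unique(y)) < 2L)
    stop("training set contains a single class", call. = FALSE)
  set.seed(seed)
  if (is.numeric(val) && length(val) == 1L && val > 0 && val < 1) {
    val_idx <- unlist(lapply(split(seq_along(y), y), function(ix)
      sample(ix, max(1L, round(length(ix) * val)))), use.names = FALSE)
  } else val_idx <- integer(0)
  tr_idx <- setdiff(seq_along(y), val_idx)
  mk_dat <- function(ix) .encode_bags(as.list(cdr3[ix]), enc, l_max,
                                      bank$entries$h, k = 1L)
  dat_tr <- mk_dat(tr_idx)
  dat_val <- if (length(val_idx)) mk_dat(val_idx) else NULL
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- seed + r - 1L
    params0 <- init_params(bank, k = NULL, seed = run_seed)
    par0 <- .params_to_par(params0)
    res <- .train_loop(par0, dat_tr, y[tr_idx], dat_val, y[val_idx],
                       level = "tcr", epochs = epochs, lr = lr,
                       dropout = dropout, patience = patience,
                       batch_size = batch_size, pooling = pooling,
                       mask_padding = mask_padding, verbose = verbose)
    va <- if (!is.null(dat_val) && length(unique(y[val_idx])) == 2L) {
      vc <- .forward(res$par, dat_val, pooling, mask_padding)
      roc_auc(vc$s, y[val_idx])$auc
    } else NA_real_
    runs[[r]] <- list(par = res$par, history = res$history, val_auc = va,
                      seed = run_seed)
  }
  best <- select_best_of_n(runs)
  structure(list(
    params = .par_to_params(best$par, bank), par = best$par, bank = bank,
    encoding = enc,
    config = list(l_max = as.integer(l_max), pooling = pooling,
                  mask_padding = mask_padding),
    history = best$history, val_auc = best$val_auc,
    runs = data.frame(seed = vapply(runs, `[[`, integer(1), "seed"),
                      val_auc = vapply(runs, `[[`, numeric(1), "val_auc"))
  ), class = "tcr_scorer_fit")
}

#' @export
predict.tcr_scorer_fit <- function(object, newdata, ...) {
  stopifnot(is.character(newdata))
  dat <- .encode_bags(as.list(newdata), object$encoding,
                      object$config$l_max, object$bank$entries$h, k = 1L)
  cc <- .forward(object$par, dat, object$config$pooling,
                 object$config$mask_padding)
  stats::setNames(cc$s, newdata)
}

#' @export
print.tcr_scorer_fit <- function(x, ...) {
  cat(sprintf("Per-TCR convolutional scorer: %d filters, d = %d, val AUC %s\n",
              x$bank$n_total, x$bank$d, format(x$val_auc, digits = 3)))
  invisible(x)
}

# ---- model persistence ------------------------------------------------------

#' Save or load a fitted repertoire classifier
#'
#' The model is written as a single self-describing JSON file bundling the
#' encoding (name, dimension and full matrix), the filter-bank layout, all
#' weights at full double precision, the preprocessing configuration and the
#' reference set, so that save -> load -> score is bit-stable.
#'
#' @param object A fitted `"tcrmil"`.
#' @param path File path.
#' @return `write_tcrmil` returns `path` invisibly; `read_tcrmil` a
#'   `"tcrmil"` object usable with `predict()`.
#' @export
write_tcrmil <- function(object, path) {
  stopifnot(inherits(object, "tcrmil"))
  par <- object$par
  payload <- list(
    format = "tcrmil-model",
    version = 1L,
    encoding = list(name = object$encoding$name, d = object$encoding$d,
                    aa = rownames(object$encoding$M),
                    M = object$encoding$M),
    bank = object$bank$entries,
    config = object$config,
    weights = list(Wf = par$Wf, bf = par$bf, WL = par$WL, bL = par$bL,
                   WLp = par$WLp, bLp = par$bLp),
    reference = if (!is.null(object$reference)) object$reference$sequences,
    reference_top_n = if (!is.null(object$reference)) object$reference$top_n,
    val_auc = object$val_auc
  )
  writeLines(jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' @rdname write_tcrmil
#' @export
read_tcrmil <- function(path) {
  p <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE)
  if (is.null(p$format) || p$format != "tcrmil-model")
    stop("not a tcrmil model file", call. = FALSE)
  M <- as.matrix(p$encoding$M)
  rownames(M) <- p$encoding$aa
  enc <- structure(list(name = p$encoding$name, d = p$encoding$d, M = M),
                   class = "aa_encoding")
  entries <- as.data.frame(p$bank)
  bank <- structure(list(entries = entries, d = enc$d,
                         n_total = sum(entries$n_filters)),
                    class = "filter_bank")
  par <- list(Wf = lapply(p$weights$Wf, as.matrix),
              bf = lapply(p$weights$bf, as.numeric),
              WL = as.numeric(p$weights$WL), bL = as.numeric(p$weights$bL),
              WLp = as.numeric(p$weights$WLp),
              bLp = as.numeric(p$weights$bLp),
              entries = entries, d = enc$d, k = p$config$k)
  reference <- if (!is.null(p$reference))
    structure(list(sequences = sort(as.character(p$reference)),
                   top_n = as.integer(p$reference_top_n)),
              class = "reference_set")
  structure(list(
    params = .par_to_params(par, bank), par = par, bank = bank,
    encoding = enc, reference = reference, config = p$config,
    history = NULL, val_auc = p$val_auc, labels = NULL,
    call = quote(read_tcrmil())
  ), class = "tcrmil")
}
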