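# Shared fixtures and independent oracles used across the test files.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_cdr3 <- function(len) {
  paste0("C", paste(sample(AA20, len - 2L, replace = TRUE), collapse = ""), "F")
}

# a repertoire with arbitrary clonotype fields for IO tests
toy_repertoire <- function(n = 5L, seed = 1L, label = NA_integer_) {
  set.seed(seed)
  repertoire(vapply(sample(10:18, n, replace = TRUE), random_cdr3, ""),
             frequency = rev(seq_len(n)), label = label,
             sample_id = paste0("s", seed))
}

# brute-force sliding-window convolution: explicit loops, no shared code path
oracle_convolve <- function(values, true_length, W, b) {
  h <- nrow(W)
  n_win <- nrow(values) - h + 1L
  out <- numeric(n_win)
  for (a in seq_len(n_win)) {
    acc <- 0
    for (t in seq_len(h))
      for (j in seq_len(ncol(W)))
        acc <- acc + W[t, j] * values[a + t - 1L, j]
    out[a] <- max(0, acc + b)
  }
  list(values = out, valid = seq_len(n_win) + h - 1L <= true_length)
}

# exhaustive z-mer scoring: the pooled max feature equals the best window
oracle_zmer_max <- function(cdr3, enc, f) {
  h <- f$h
  L <- nchar(cdr3)
  best <- -Inf
  for (a in seq_len(L - h + 1L)) {
    zmer <- substr(cdr3, a, a + h - 1L)
    M <- enc$M[strsplit(zmer, "")[[1]], , drop = FALSE]
    best <- max(best, sum(f$W * M) + f$b)
  }
  max(0, best)
}

# Mann-Whitney pairwise AUC oracle
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  mean(cmp)
}

oracle_confusion <- function(scores, labels, thr) {
  pred <- as.integer(scores > thr)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  list(accuracy = (tp + tn) / length(labels),
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

# exhaustive threshold sweep for Youden / sensitivity-at-specificity
oracle_sweep <- function(scores, labels) {
  u <- sort(unique(scores))
  mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  cand <- c(-Inf, mids, u[length(u)])
  sens <- vapply(cand, function(t) mean(scores[labels == 1] > t), 0)
  spec <- vapply(cand, function(t) mean(scores[labels == 0] <= t), 0)
  list(cand = cand, sens = sens, spec = spec, J = sens + spec - 1)
}

default_bank <- function(d = 5L) design_filter_bank(contact_region_table(), d = d)

tiny_cohort <- function(n_per = 8L, seqs = 20L, seed = 1L, witness_rate = 0.2) {
  generate_cohort(n_cancer = n_per, n_control = n_per, seqs_per_sample = seqs,
                  witness_rate = witness_rate, seed = seed)
}

cohort_labels <- function(reps) vapply(reps, function(r) r$label, integer(1))
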