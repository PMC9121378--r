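test_that("AUC matches ranking intuition on worked examples", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  # 3 of 4 positive/negative pairs ranked correctly
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))$auc, 0.75)
  # all-tied scores carry no ranking information
  expect_equal(roc_auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_error(roc_auc(runif(4), c(1, 1, 1, 1)), "both classes")
})

test_that("trapezoid AUC equals the Mann-Whitney statistic on random instances", {
  set.seed(40)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # inject ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    expect_lt(abs(r$auc - oracle_auc(scores, labels)), 1e-10)
    # the curve integrates to its own AUC and fpr is monotone
    tr <- sum(diff(r$points$fpr) *
                (head(r$points$tpr, -1) + tail(r$points$tpr, -1)) / 2)
    expect_lt(abs(tr - r$auc), 1e-10)
    expect_true(all(diff(r$points$fpr) >= 0))
  }
})

test_that("sensitivity at fixed specificity matches an exhaustive sweep", {
  set.seed(41)
  for (i in 1:40) {
    n <- sample(6:150, 1)
    scores <- round(runif(n), 2)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    for (target in c(0.5, 0.9, 1.0)) {
      got <- sensitivity_at_specificity(scores, labels, target)
      sw <- oracle_sweep(scores, labels)
      ok <- sw$spec >= target
      expect_equal(got$sensitivity, max(sw$sens[ok]))
      expect_gte(got$specificity, target)
    }
  }
  # perfectly separated classes: full sensitivity at any target
  got <- sensitivity_at_specificity(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0.9)
  expect_equal(got$sensitivity, 1.0)
  # impossible-to-beat target still yields the all-negative operating point
  got2 <- sensitivity_at_specificity(rep(0.5, 4), c(1, 1, 0, 0), 1.0)
  expect_equal(got2$sensitivity, 0)
  expect_equal(got2$specificity, 1)
})

test_that("the Youden threshold maximizes J and resolves ties downward", {
  # separable scores: the gap midpoint attains J = 1
  thr <- youden_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(as.numeric(thr), 0.5)
  expect_equal(attr(thr, "J"), 1.0)
  # degenerate: identical scores give J = 0
  thr0 <- youden_threshold(rep(0.3, 4), c(1, 0, 1, 0))
  expect_equal(attr(thr0, "J"), 0.0)
  expect_error(youden_threshold(runif(3), c(1, 1, 1)), "both classes")

  set.seed(42)
  for (i in 1:40) {
    n <- sample(8:150, 1)
    scores <- round(runif(n), 2)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    thr <- youden_threshold(scores, labels)
    sw <- oracle_sweep(scores, labels)
    expect_equal(attr(thr, "J"), max(sw$J), tolerance = 1e-12)
    # ties resolve to the lowest candidate threshold
    expect_equal(as.numeric(thr),
                 min(sw$cand[abs(sw$J - max(sw$J)) < 1e-12]))
  }
})

test_that("confusion metrics use a strictly-greater-than threshold", {
  m <- confusion_metrics(c(0.6, 0.4), c(1, 0), 0.5)
  expect_equal(m$accuracy, 1.0)
  expect_equal(m$sensitivity, 1.0)
  expect_equal(m$specificity, 1.0)
  # a score exactly at the threshold is predicted negative
  m2 <- confusion_metrics(c(0.5, 0.4), c(1, 0), 0.5)
  expect_equal(m2$sensitivity, 0.0)
  expect_equal(m2$specificity, 1.0)

  set.seed(43)
  scores <- runif(20); labels <- rbinom(20, 1, 0.5); thr <- 0.4
  want <- oracle_confusion(scores, labels, thr)
  got <- confusion_metrics(scores, labels, thr)
  expect_equal(got$accuracy, want$accuracy)
  expect_equal(got$sensitivity, want$sensitivity)
  expect_equal(got$specificity, want$specificity)
})

# a trivial deterministic "model" so cross-validation mechanics can be tested
# without network training: scores a repertoire by its mean sequence length
fit_mock <- function(x, labels, val, val_labels, seed, noise = 0, ...) {
  structure(list(noise = noise, seed = seed), class = "tcrmil_mockfit")
}
assign("predict.tcrmil_mockfit", function(object, newdata, ...) {
  vapply(newdata, function(r) {
    s <- mean(nchar(r$clonotypes$cdr3)) / 24
    if (object$noise > 0) s + rnorm(1, sd = object$noise) else s
  }, numeric(1))
}, envir = globalenv())

test_that("cross-validation produces folds x repeats evaluations, seeded", {
  cohort <- tiny_cohort(n_per = 10L, seqs = 10L, seed = 2)
  labs <- cohort_labels(cohort$repertoires)
  cv1 <- cross_validate(cohort$repertoires, labs, folds = 5L, repeats = 2L,
                        seed = 7, fit_fun = fit_mock)
  expect_equal(nrow(cv1$results), 10L)
  expect_equal(nrow(cv1$predictions), 2L * length(labs))
  # deterministic model + same seed -> identical results
  cv2 <- cross_validate(cohort$repertoires, labs, folds = 5L, repeats = 2L,
                        seed = 7, fit_fun = fit_mock)
  expect_identical(cv1$results, cv2$results)
  # aggregate carries one row per metric with finite CI bounds
  expect_setequal(cv1$aggregate$metric,
                  c("auc", "accuracy", "sensitivity", "specificity"))
  expect_true(all(cv1$aggregate$ci_lo <= cv1$aggregate$ci_hi))
})

test_that("nested cross-validation runs the inner model-selection loop", {
  cohort <- tiny_cohort(n_per = 6L, seqs = 10L, seed = 3)
  labs <- cohort_labels(cohort$repertoires)
  cv <- cross_validate(cohort$repertoires, labs, folds = 3L, repeats = 2L,
                       nested = TRUE, seed = 5, fit_fun = fit_mock)
  expect_equal(nrow(cv$results), 6L)
  expect_true(all(is.finite(cv$results$auc)))
})

test_that("stratification fails loudly when a class cannot fill the folds", {
  cohort <- tiny_cohort(n_per = 6L, seqs = 10L, seed = 4)
  labs <- cohort_labels(cohort$repertoires)
  labs[labs == 1][-1] <- 0L   # a single positive cannot stratify 5 folds
  expect_error(cross_validate(cohort$repertoires, labs, folds = 5L,
                              repeats = 1L, fit_fun = fit_mock),
               "stratification|at least")
})

test_that("the CV confidence interval shrinks with more repeats", {
  cohort <- tiny_cohort(n_per = 10L, seqs = 10L, seed = 6)
  labs <- cohort_labels(cohort$repertoires)
  hw <- vapply(c(2L, 8L), function(reps) {
    cv <- cross_validate(cohort$repertoires, labs, folds = 5L,
                         repeats = reps, seed = 11, fit_fun = fit_mock,
                         noise = 0.3)
    agg <- cv$aggregate
    row <- agg[agg$metric == "auc", ]
    (row$ci_hi - row$ci_lo) / 2
  }, numeric(1))
  # 4x the repeats: expect roughly half the half-width (allow wide slack)
  expect_lt(hw[2], hw[1] * 0.85)
})
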