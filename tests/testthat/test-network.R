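test_that("convolution windows match a brute-force dot-product oracle", {
  set.seed(30)
  for (i in 1:10) {
    d <- 3L
    vals <- matrix(rnorm(6 * d), 6, d)
    M <- structure(list(values = vals, true_length = 6L,
                        mask = rep(TRUE, 6)), class = "tcr_matrix")
    f <- conv_filter(matrix(rnorm(2 * d), 2, d), b = rnorm(1))
    got <- convolve(M, f)
    want <- oracle_convolve(vals, 6L, f$W, f$b)
    expect_lt(max(abs(got$values - want$values)), 1e-10)
    expect_identical(got$valid, want$valid)
  }
})

test_that("a height-2 filter over an 11-residue sequence gives a 10-window map", {
  enc <- load_encoding("atchley")
  M <- encode_sequence("CASSLGQAYEQ", enc, l_max = 11L)
  f <- conv_filter(matrix(0.1, 2, 5))
  expect_length(convolve(M, f)$values, 10L)
  # padded to 24 the map lengthens but only 10 windows stay valid
  M24 <- encode_sequence("CASSLGQAYEQ", enc, l_max = 24L)
  fm <- convolve(M24, f)
  expect_length(fm$values, 23L)
  expect_equal(sum(fm$valid), 10L)
})

test_that("ReLU clips negative responses to zero", {
  M <- structure(list(values = matrix(0, 11, 5), true_length = 11L,
                      mask = rep(TRUE, 11)), class = "tcr_matrix")
  f <- conv_filter(matrix(1, 2, 5), b = -1)
  expect_identical(convolve(M, f)$values, rep(0, 10))
  expect_error(convolve(structure(list(values = matrix(0, 11, 5),
                                       true_length = 1L,
                                       mask = c(TRUE, rep(FALSE, 10))),
                                  class = "tcr_matrix"), f), "shorter")
})

test_that("pooling reductions take the stated values", {
  fm <- structure(list(values = c(0.1, 0.9, 0.3), valid = rep(TRUE, 3)),
                  class = "feature_map")
  expect_equal(pool(fm, "max"), 0.9)
  expect_equal(pool(fm, "avg"), mean(c(0.1, 0.9, 0.3)))
  expect_equal(pool(structure(list(values = c(0, 1), valid = c(TRUE, TRUE)),
                              class = "feature_map"), "lse"),
               log((exp(0) + exp(1)) / 2), tolerance = 1e-12)
  # constant maps reduce to the constant under every mode
  cm <- structure(list(values = rep(0.4, 5), valid = rep(TRUE, 5)),
                  class = "feature_map")
  for (mode in c("max", "avg", "lse"))
    expect_equal(pool(cm, mode), 0.4, tolerance = 1e-12)
  # masking drops padding-overlapping windows
  fm2 <- structure(list(values = c(0.2, 5), valid = c(TRUE, FALSE)),
                   class = "feature_map")
  expect_equal(pool(fm2, "max"), 0.2)
  expect_equal(pool(fm2, "max", mask_padding = FALSE), 5)
  expect_error(pool(structure(list(values = 1, valid = FALSE),
                              class = "feature_map"), "max"), "eligible")
})

test_that("pooling obeys max >= avg >= 0 and lse <= max on ReLU maps", {
  set.seed(31)
  for (i in 1:25) {
    v <- pmax(rnorm(sample(3:12, 1)), 0)
    fm <- structure(list(values = v, valid = rep(TRUE, length(v))),
                    class = "feature_map")
    expect_gte(pool(fm, "max"), pool(fm, "avg"))
    expect_gte(pool(fm, "avg"), 0)
    expect_lte(pool(fm, "lse"), pool(fm, "max"))
  }
})

test_that("the default bank pools to a 14-dimensional feature vector", {
  enc <- load_encoding("atchley")
  params <- init_params(default_bank(), seed = 1)
  M <- encode_sequence("CASSLGQAYEQYF", enc)
  p <- feature_vector(M, params)
  expect_length(p, 14L)

  zero <- params
  zero$filters <- lapply(zero$filters, function(f) conv_filter(f$W * 0, 0))
  expect_identical(feature_vector(M, zero), rep(0, 14))
})

test_that("pooled features equal exhaustive z-mer window scoring", {
  enc <- load_encoding("atchley")
  params <- init_params(default_bank(), seed = 2)
  set.seed(32)
  for (i in 1:10) {
    cdr3 <- random_cdr3(sample(10:24, 1))
    M <- encode_sequence(cdr3, enc)
    p <- feature_vector(M, params, mode = "max", mask_padding = TRUE)
    want <- vapply(params$filters, function(f) oracle_zmer_max(cdr3, enc, f),
                   numeric(1))
    expect_lt(max(abs(p - want)), 1e-8)
  }
})

test_that("the per-TCR score is the sigmoid of the linear classifier", {
  bank <- default_bank()
  params <- init_params(bank, seed = 1)
  params$W_L <- rep(0, 14); params$b_L <- 0
  expect_equal(tcr_score(runif(14), params), 0.5)
  params$W_L <- rep(0.1, 14); params$b_L <- -0.7
  expect_equal(tcr_score(rep(1, 14), params), 1 / (1 + exp(-0.7)),
               tolerance = 1e-12)
  params$b_L <- 1e4   # saturation limit
  expect_equal(tcr_score(rep(1, 14), params), 1, tolerance = 1e-12)
  expect_error(tcr_score(rep(1, 3), params), "length")
})

test_that("cross-entropy losses take their closed-form values", {
  expect_equal(tcr_loss(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(tcr_loss(0.5, 0), log(2), tolerance = 1e-12)
  expect_equal(tcr_loss(0.8, 1), -log(0.8), tolerance = 1e-12)
  expect_equal(mil_loss(0.9, 0), -log(0.1), tolerance = 1e-12)
  # clamping keeps perfect predictions finite and near zero
  expect_lt(tcr_loss(1, 1), 1e-10)
  expect_true(is.finite(tcr_loss(0, 1)))
})

test_that("bag aggregation is the sigmoid-weighted rank combination", {
  bank <- default_bank()
  params <- init_params(bank, k = 4L, seed = 1)
  params$W_Lp <- rep(0, 4); params$b_Lp <- 0
  expect_equal(bag_score(runif(4), params)$Y_hat, 0.5)
  params$W_Lp <- c(2, 0, 0, 0); params$b_Lp <- -1
  bp <- bag_score(c(0.9, 0.1, 0.2, 0.1), params)
  expect_equal(bp$Y_hat, 1 / (1 + exp(-0.8)), tolerance = 1e-12)
  expect_equal(bp$label_pred, 1L)
  expect_error(bag_score(runif(3), params), "expected 4")

  # uniform weights recover a calibrated mean aggregator
  params$W_Lp <- rep(1 / 4, 4); params$b_Lp <- 0
  s <- c(0.2, 0.4, 0.6, 0.8)
  expect_equal(bag_score(s, params)$Y_hat, 1 / (1 + exp(-mean(s))),
               tolerance = 1e-12)
})

test_that("baseline aggregators are the mean and the max of the scores", {
  expect_equal(baseline_aggregate(c(0.2, 0.8), "mean"), 0.5)
  expect_equal(baseline_aggregate(c(0.2, 0.8), "max"), 0.8)
  set.seed(33)
  for (i in 1:10) {
    s <- runif(sample(2:20, 1))
    expect_lte(baseline_aggregate(s, "mean"), baseline_aggregate(s, "max"))
  }
  expect_error(baseline_aggregate(numeric(0)), "no scores")
})

test_that("forward_bag scores a preprocessed repertoire deterministically", {
  enc <- load_encoding("atchley")
  params <- init_params(default_bank(), k = 5L, seed = 3)
  rep <- toy_repertoire(n = 5L, seed = 5)

  zero <- params
  zero$filters <- lapply(zero$filters, function(f) conv_filter(f$W * 0, 0))
  zero$W_L <- rep(0, 14); zero$b_L <- 0
  zero$W_Lp <- rep(0, 5); zero$b_Lp <- 0
  expect_equal(forward_bag(rep, zero, enc)$Y_hat, 0.5)

  # a bag of identical sequences has constant per-TCR scores
  same <- repertoire(rep("CASSLGQAYEQYF", 5), rep(0.2, 5))
  bp <- forward_bag(same, params, enc)
  expect_equal(length(unique(round(bp$tcr_scores, 12))), 1L)

  # deterministic: two calls agree exactly
  bp2 <- forward_bag(same, params, enc)
  expect_identical(bp$Y_hat, bp2$Y_hat)
})

test_that("masked scores are invariant to padding length", {
  enc <- load_encoding("atchley")
  params <- init_params(default_bank(), seed = 4)
  set.seed(34)
  for (i in 1:8) {
    cdr3 <- random_cdr3(sample(10:20, 1))
    p24 <- feature_vector(encode_sequence(cdr3, enc, 24L), params,
                          mask_padding = TRUE)
    pnat <- feature_vector(encode_sequence(cdr3, enc, nchar(cdr3)), params,
                           mask_padding = TRUE)
    expect_equal(p24, pnat, tolerance = 1e-12)
  }
})

test_that("scores are invariant to permuting filters within one height", {
  enc <- load_encoding("atchley")
  params <- init_params(default_bank(), seed = 5)
  M <- encode_sequence("CASSLGQAYEQYF", enc)
  # swap the first two height-2 filters and the matching classifier weights
  perm <- params
  perm$filters[c(1, 2)] <- params$filters[c(2, 1)]
  perm$W_L[c(1, 2)] <- params$W_L[c(2, 1)]
  s0 <- tcr_score(feature_vector(M, params), params)
  s1 <- tcr_score(feature_vector(M, perm), perm)
  expect_equal(s0, s1, tolerance = 1e-12)
})

test_that("the batched training forward equals the per-sequence reference path", {
  enc <- load_encoding("atchley")
  bank <- default_bank()
  params <- init_params(bank, k = 4L, seed = 6)
  ns <- asNamespace("tcrmil")
  bags <- list(c("CASSLGQAYEQYF", "CASSLAPGATNEKLFF"),
               c("CASRGNTEAFFEQFF", "CAWSVQETQYF", "CASSPGQGAYEQYF"))
  par <- ns$.params_to_par(params)
  dat <- ns$.encode_bags(bags, enc, 24L, bank$entries$h, 4L)
  for (pl in c("max", "avg", "lse")) {
    cache <- ns$.forward(par, dat, pl, TRUE)
    ref <- vapply(bags, function(b) {
      rp <- repertoire(b, rep(1 / length(b), length(b)), normalize = FALSE)
      forward_bag(rp, params, enc, mode = pl)$Y_hat
    }, numeric(1))
    expect_equal(unname(cache$Yhat), ref, tolerance = 1e-12)
  }
})
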