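test_that("simple TSV counts are normalized to clonal fractions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cdr3\tcount\tv_gene",
               "CASSLAPGATNEKLFF\t6\tTRBV5-1",
               "CASSLGQAYEQYF\t3\tTRBV9",
               "CASSPDRGAYGYTF\t1\tTRBV28"), path)
  rep <- parse_repertoire(path, "simple")
  expect_equal(rep$clonotypes$frequency, c(0.6, 0.3, 0.1))
  expect_true(all(rep$clonotypes$v_resolved))
})

test_that("a blank V-gene column keeps the clonotype but flags it unresolved", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cdr3\tcount\tv_gene",
               "CASSLAPGATNEKLFF\t6\tTRBV5-1",
               "CASSLGQAYEQYF\t3\t",
               "CASSPDRGAYGYTF\t1\tunresolved"), path)
  rep <- parse_repertoire(path, "simple")
  expect_equal(nrow(rep$clonotypes), 3L)
  expect_equal(rep$clonotypes$v_resolved, c(TRUE, FALSE, FALSE))
})

test_that("missing mandatory columns and empty files are format errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence\tcount\tv_gene", "CASSF\t1\tTRBV9"), path)
  expect_error(parse_repertoire(path, "simple"), "CDR3")
  writeLines("cdr3\tcount\tv_gene", path)
  expect_error(parse_repertoire(path, "simple"), "empty")
})

test_that("immuneACCESS and AIRR dialects parse with their native columns", {
  ia <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# exported sample",
               "amino_acid\tproductive_frequency\tv_gene",
               "CASSLAPGATNEKLFF\t0.5\tTCRBV05-01",
               "CASSLGQAYEQYF\t0.3\tunresolved"), ia)
  rep <- parse_repertoire(ia, "immuneaccess")
  expect_equal(rep$clonotypes$frequency, c(0.5, 0.3))
  expect_equal(rep$clonotypes$v_resolved, c(TRUE, FALSE))

  airr <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("junction_aa\tduplicate_count\tv_call",
               "CASSLAPGATNEKLFF\t8\tTRBV5-1*01",
               "CASSLGQAYEQYF\t2\tTRBV9*01"), airr)
  rep2 <- parse_repertoire(airr, "airr")
  expect_equal(rep2$clonotypes$frequency, c(0.8, 0.2))
})

test_that("quality filter applies the four removal rules and keeps order", {
  cl <- data.frame(
    cdr3 = c("CASSLGF",              # too short (< 10)
             "CASSLAPGATNEKLFF",     # passes
             "CASSL*GELFF",          # special character
             "CASSLXGELFF",          # X counts as special
             "AASSLAPGATNEKLFF",     # does not start with C
             "CASSLAPGATNEKLFC",     # does not end with F
             "CASSLGQAYEQYF",        # passes
             paste0("C", strrep("A", 24), "F")),  # too long (> 24)
    frequency = rep(0.1, 8),
    v_resolved = TRUE, v_gene = "TRBV9",
    stringsAsFactors = FALSE
  )
  out <- qc_filter(cl)
  expect_equal(out$cdr3, c("CASSLAPGATNEKLFF", "CASSLGQAYEQYF"))

  cl$v_resolved[2] <- FALSE   # rule 4: unresolved V locus
  expect_equal(qc_filter(cl)$cdr3, "CASSLGQAYEQYF")
})

test_that("quality filter is idempotent on random repertoires", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30L
    cl <- data.frame(
      cdr3 = replicate(n, {
        s <- random_cdr3(sample(8:26, 1))
        if (runif(1) < 0.2) sub("S", "*", s) else s
      }),
      frequency = runif(n),
      v_resolved = runif(n) > 0.3, v_gene = "TRBV9",
      stringsAsFactors = FALSE
    )
    once <- qc_filter(cl)
    expect_identical(qc_filter(once), once)
  }
})

test_that("reference set holds sequences abundant in both classes only", {
  shared <- "CASSSHAREDAEQFF"
  canc_only <- "CASSCANCERONLYF"
  mk <- function(seqs, label, id)
    repertoire(seqs, frequency = rev(seq_along(seqs)), sample_id = id,
               label = label)
  cancer1 <- mk(c(shared, canc_only, random_cdr3(14)), 1L, "c1")
  cancer2 <- mk(c(canc_only, random_cdr3(15)), 1L, "c2")
  healthy <- mk(c(shared, random_cdr3(13)), 0L, "h1")
  ref <- build_reference_set(list(cancer1, cancer2, healthy), top_n = 3L)
  expect_true(shared %in% ref$sequences)
  expect_false(canc_only %in% ref$sequences)

  # invariant to sample order
  ref2 <- build_reference_set(list(healthy, cancer2, cancer1), top_n = 3L)
  expect_identical(ref$sequences, ref2$sequences)

  # top_n = 1 with distinct per-sample top sequences -> empty set
  healthy2 <- mk(c(random_cdr3(16), shared), 0L, "h2")
  ref3 <- build_reference_set(list(cancer1, cancer2, healthy2), top_n = 1L)
  expect_length(ref3$sequences, 0L)

  expect_error(build_reference_set(list(cancer1, cancer2)), "non-cancer")
})

test_that("top-k selection removes reference hits and breaks ties lexicographically", {
  shared <- "CASSSHAREDAEQFF"
  rep <- repertoire(
    c("CASSBETAF0000F", shared, "CASSALPHAF000F", "CASSGAMMAF000F",
      "CASSDELTAF000F"),
    frequency = c(0.3, 0.25, 0.3, 0.1, 0.05),
    normalize = FALSE
  )
  # make all cdr3 valid-alphabet strings
  rep$clonotypes$cdr3 <- c("CASSWGQETQYFAF", shared, "CASSAGQETQYFAF",
                           "CASSGGQETQYFAF", "CASSDGQETQYFAF")
  ref <- structure(list(sequences = shared, top_n = 3L),
                   class = "reference_set")
  top <- select_top_k(rep, k = 3L, reference = ref)
  expect_equal(nrow(top$clonotypes), 3L)
  expect_false(shared %in% top$clonotypes$cdr3)
  # tie at 0.3 broken toward the lexicographically smaller sequence,
  # matching an explicit stable-sort oracle
  cl <- rep$clonotypes[rep$clonotypes$cdr3 != shared, ]
  oracle <- cl[order(-cl$frequency, cl$cdr3), "cdr3"]
  expect_equal(top$clonotypes$cdr3, oracle[1:3])
  expect_equal(top$clonotypes$cdr3[1], "CASSAGQETQYFAF")
})

test_that("top-k output is bounded by k with non-increasing frequencies", {
  for (seed in 1:5) {
    rep <- toy_repertoire(n = 12L, seed = seed)
    k <- sample(1:15, 1)
    out <- select_top_k(rep, k)
    expect_lte(nrow(out$clonotypes), k)
    expect_true(all(diff(out$clonotypes$frequency) <= 0))
  }
  # k beyond the survivor count returns all survivors without padding
  rep <- toy_repertoire(n = 4L, seed = 9)
  expect_equal(nrow(select_top_k(rep, 10L)$clonotypes), 4L)
})

test_that("a repertoire survives a write/parse round trip exactly", {
  rep <- toy_repertoire(n = 8L, seed = 3, label = 1L)
  rep$clonotypes$frequency <- rep$clonotypes$frequency /
    sum(rep$clonotypes$frequency)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_repertoire(rep, path)
  back <- parse_repertoire(path, "simple", sample_id = rep$sample_id,
                           label = 1L)
  expect_identical(back$clonotypes$cdr3, rep$clonotypes$cdr3)
  expect_identical(back$clonotypes$frequency, rep$clonotypes$frequency)
  expect_identical(back$label, rep$label)
})

test_that("reference sets round-trip through one-sequence-per-line text", {
  ref <- structure(list(sequences = sort(c("CASSLGQAYEQYF", "CASSLAPGATNEKLFF")),
                        top_n = 10L), class = "reference_set")
  path <- withr::local_tempfile(fileext = ".txt")
  write_reference_set(ref, path)
  back <- read_reference_set(path, top_n = 10L)
  expect_identical(back$sequences, ref$sequences)
})
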