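test_that("LDA separates well-separated classes and validates input", {
  set.seed(1)
  xtr <- rbind(matrix(rnorm(50, -10), 10), matrix(rnorm(50, 10), 10))
  ytr <- rep(1:2, each = 10)
  expect_identical(classify_lda(xtr, ytr, matrix(9.5, 1, 5)), 2L)
  expect_identical(classify_lda(xtr, ytr, matrix(-9.5, 1, 5)), 1L)

  expect_error(classify_lda(xtr[1:10, ], ytr[1:10], xtr), "2 classes")
  xtr_bad <- xtr
  xtr_bad[1, 1] <- NaN
  expect_error(classify_lda(xtr_bad, ytr, xtr), "non-finite")
})

test_that("LDA is equivariant under training-sample permutation", {
  set.seed(2)
  xtr <- matrix(rnorm(60), 12, 5)
  ytr <- rep(1:3, 4)
  xte <- matrix(rnorm(20), 4, 5)
  ref <- classify_lda(xtr, ytr, xte)
  for (i in 1:5) {
    perm <- sample(12)
    expect_identical(classify_lda(xtr[perm, ], ytr[perm], xte), ref)
  }
})

test_that("classifiers hit 1.0 on separable data and chance under null", {
  set.seed(3)
  # noiseless linearly separated classes
  centers <- matrix(c(5, 0, 0, 0, 5, 0, 0, 0, 5), 3, byrow = TRUE)
  ytr <- rep(1:3, each = 4)
  xtr <- centers[ytr, ] + matrix(rnorm(36, sd = 1e-3), 12, 3)
  xte <- centers[rep(1:3, 2), ]
  expect_identical(classify_lda(xtr, ytr, xte), rep(1:3, 2))
  expect_identical(classify_naive_bayes(xtr, ytr, xte), rep(1:3, 2))

  # label-permuted training: accuracy approximately 1/C
  n_correct <- 0
  n_total <- 0
  for (s in 1:60) {
    set.seed(100 + s)
    xtr <- matrix(rnorm(60), 12, 5)
    yperm <- sample(rep(1:2, 6))
    xte <- matrix(rnorm(40), 8, 5)
    yte <- rep(1:2, 4)
    n_correct <- n_correct + sum(classify_lda(xtr, yperm, xte) == yte)
    n_total <- n_total + 8
  }
  ci <- qnorm(0.995) * sqrt(0.25 / n_total)
  expect_lt(abs(n_correct / n_total - 0.5), ci)
})

test_that("naive Bayes uses empirical priors and survives constants", {
  set.seed(4)
  # identical class-conditional distributions, 3:1 prior imbalance
  xtr <- matrix(rnorm(80), 20, 4)
  ytr <- rep(c(1, 2), c(15, 5))
  pred <- classify_naive_bayes(xtr, ytr, matrix(rnorm(40), 10, 4))
  expect_true(mean(pred == 1) > 0.5)

  # constant feature: variance floor, no crash
  xtr[, 2] <- 7
  expect_silent(classify_naive_bayes(xtr, ytr, matrix(rnorm(8), 2, 4)))
})

test_that("partition schemes produce the expected folds", {
  ds <- make_tiny_ds(n_targets = 3, n_chunks = 4)
  nf <- make_partitions(ds, "nfold")
  expect_equal(length(nf$folds), 4)
  for (fold in nf$folds) {
    expect_equal(length(unique(ds$sa$chunks[fold$test])), 1)
    expect_setequal(union(fold$train, fold$test), seq_len(12))
  }

  tko <- make_partitions(ds, "take_k_out", k = 2)
  expect_equal(length(tko$folds), 6)
  test_chunk_sets <- lapply(tko$folds, function(f) {
    sort(unique(ds$sa$chunks[f$test]))
  })
  expect_equal(test_chunk_sets, combn(1:4, 2, sort, simplify = FALSE))

  oe <- make_partitions(ds, "oddeven")
  expect_equal(length(oe$folds), 2)
  expect_setequal(unique(ds$sa$chunks[oe$folds[[1]]$train]), c(1, 3))
  expect_setequal(unique(ds$sa$chunks[oe$folds[[1]]$test]), c(2, 4))

  expect_error(make_partitions(ds, "take_k_out", k = 4), "k must be")
  single <- slice_dataset(ds, ds$sa$chunks == 1, "samples")
  expect_error(make_partitions(single, "nfold"), "at least 2")
})

test_that("cross-group partitions never mix groups across train/test", {
  ds <- make_tiny_ds(n_targets = 2, n_chunks = 4)
  two <- stack_datasets(list(ds, ds), "samples")
  two$sa$modality <- rep(1:2, each = 8)
  p <- make_partitions(two, "cross_grouped", group = "modality")
  expect_equal(length(p$folds), 8)  # 2 ordered pairs x 4 chunks
  for (fold in p$folds) {
    expect_equal(length(unique(two$sa$modality[fold$train])), 1)
    expect_equal(length(unique(two$sa$modality[fold$test])), 1)
    expect_false(unique(two$sa$modality[fold$train]) ==
                   unique(two$sa$modality[fold$test]))
    expect_equal(length(intersect(two$sa$chunks[fold$train],
                                  two$sa$chunks[fold$test])), 0)
  }
  expect_identical(check_partitions(p, two), character(0))
  expect_error(make_partitions(two, "cross_grouped", group = "nope"),
               "group attribute")
})

test_that("check_partitions flags structural violations", {
  ds <- make_tiny_ds(n_targets = 2, n_chunks = 4)
  good <- make_partitions(ds, "nfold")
  expect_identical(check_partitions(good, ds), character(0))

  overlap <- structure(list(folds = list(list(train = 1:6, test = 5:8))),
                       class = "mvpa_partitions")
  v <- check_partitions(overlap, ds)
  expect_match(v, "overlap", all = FALSE)
  expect_match(v, "chunk", all = FALSE)

  # slice one class out of the training side
  class1 <- which(ds$sa$targets == 1 & ds$sa$chunks != 4)
  lop <- structure(list(folds = list(list(
    train = class1, test = which(ds$sa$chunks == 4)))),
    class = "mvpa_partitions")
  expect_match(check_partitions(lop, ds), "missing from training",
               all = FALSE)
})

test_that("make_partitions output always passes check_partitions", {
  for (n_chunks in c(2, 4, 5)) {
    ds <- make_tiny_ds(n_targets = 2, n_chunks = n_chunks,
                       seed = n_chunks)
    for (scheme in c("nfold", "oddeven")) {
      p <- make_partitions(ds, scheme)
      expect_identical(check_partitions(p, ds), character(0))
    }
    p <- make_partitions(ds, "take_k_out", k = 1)
    expect_identical(check_partitions(p, ds), character(0))
  }
})
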