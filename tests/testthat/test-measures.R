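# behavioral pairwise dissimilarity matrix for six animal categories,
# used as an RSA target
behaviour_dissimilarity <- matrix(c(
     0, 0.10, 1.05, 1.10, 1.68, 1.75,
  0.10,    0, 1.04, 1.05, 1.70, 1.76,
  1.05, 1.04,    0, 0.39, 1.54, 1.46,
  1.10, 1.05, 0.39,    0, 1.47, 1.40,
  1.68, 1.70, 1.54, 1.47,    0, 0.16,
  1.75, 1.76, 1.46, 1.40, 0.16,    0), 6, 6, byrow = TRUE)

test_that("cross-validation measure pools accuracy over folds", {
  # identical class patterns in all chunks, no noise: perfect decoding
  patterns <- matrix(c(1, 0, 0, 1, 1, 1, 0, 0), 2, byrow = TRUE)
  ds <- mvpa_dataset(patterns[rep(1:2, 4), ],
                     targets = rep(1:2, 4), chunks = rep(1:4, each = 2))
  res <- crossvalidation_measure(ds, list(classifier = classify_lda))
  expect_equal(dim(res$samples), c(1, 1))
  expect_equal(res$samples[1, 1], 1.0)
  expect_identical(validate_dataset(res), character(0))

  pred <- crossvalidation_measure(ds, list(output = "predictions"))
  expect_equal(dim(pred$samples), c(8, 1))
  expect_true(all(pred$samples[, 1] %in% 1:2))
  expect_identical(pred$sa$targets, ds$sa$targets)
  expect_identical(pred$samples[, 1], as.numeric(ds$sa$targets))
})

test_that("cross-validation supports train-estimated normalization", {
  ds <- make_tiny_ds(n_targets = 2, n_chunks = 4, effect = 3, seed = 20)
  plain <- crossvalidation_measure(ds, list())
  zs <- crossvalidation_measure(ds, list(normalization = "zscore"))
  expect_true(zs$samples[1, 1] >= 0 && zs$samples[1, 1] <= 1)
  expect_true(plain$samples[1, 1] > 0.8)  # strong effect decodes
})

test_that("cross-validation propagates classifier errors with context", {
  ds <- make_tiny_ds()
  boom <- function(...) stop("kaput")
  expect_error(crossvalidation_measure(ds, list(classifier = boom)),
               "fold 1: kaput")
  bad <- structure(list(folds = list(list(train = 1:8, test = 1:4))),
                   class = "mvpa_partitions")
  expect_error(crossvalidation_measure(ds, list(partitions = bad)),
               "invalid partitions")
})

test_that("split-half correlation contrasts within vs between targets", {
  set.seed(21)
  base <- matrix(rnorm(2 * 30), 2)    # orthogonal-ish class patterns
  half1 <- base[rep(1:2, 2), ] + matrix(rnorm(120, sd = 0.01), 4)
  half2 <- base[rep(1:2, 2), ] + matrix(rnorm(120, sd = 0.01), 4)
  ds <- mvpa_dataset(rbind(half1, half2),
                     targets = rep(rep(1:2, 2), 2),
                     chunks = rep(1:2, each = 4))
  res <- correlation_measure(ds)
  expect_equal(dim(res$samples), c(1, 1))
  expect_gt(res$samples[1, 1], 0)

  # brute-force oracle on 3-class data with 4 chunks (chunkized halves)
  set.seed(22)
  ds3 <- make_tiny_ds(n_targets = 3, n_chunks = 4, effect = 1, seed = 22)
  got <- correlation_measure(ds3)$samples[1, 1]
  half <- chunkize(ds3, 2)
  m <- function(h) t(sapply(1:3, function(tg) {
    colMeans(ds3$samples[half == h & ds3$sa$targets == tg, , drop = FALSE])
  }))
  z12 <- atanh(cor(t(m(1)), t(m(2))))
  w <- matrix(-1 / 6, 3, 3)
  diag(w) <- 1 / 3
  expected <- (sum(w * z12) + sum(w * t(z12))) / 2
  expect_equal(got, expected, tolerance = 1e-12)

  # missing target in one half
  lop <- slice_dataset(ds3, !(half == 1 & ds3$sa$targets == 2), "samples")
  expect_error(correlation_measure(lop), "missing from half")
})

test_that("perfect correlations are clamped before Fisher transform", {
  patterns <- matrix(c(1, 0, 1, 0, 0, 1, 0, 1), 2, byrow = TRUE)
  ds <- mvpa_dataset(patterns[rep(1:2, 2), ],
                     targets = rep(1:2, 2), chunks = rep(1:2, each = 2))
  expect_warning(res <- correlation_measure(ds), "clamped")
  expect_true(is.finite(res$samples[1, 1]))
})

test_that("RSA measure correlates neural and target dissimilarities", {
  set.seed(23)
  x <- matrix(rnorm(6 * 40), 6)
  ds <- mvpa_dataset(x, targets = 1:6, chunks = rep(1, 6))

  # self-correlation: neural DSM as its own target gives exactly 1
  neural <- 1 - cor(t(x))
  self <- target_dsm_corr_measure(ds, list(target_dsm = neural))
  expect_equal(self$samples[1, 1], 1.0)

  # brute-force upper-triangle correlation against the behavioral matrix
  res <- target_dsm_corr_measure(
    ds, list(target_dsm = behaviour_dissimilarity))
  ut <- function(m) m[upper.tri(m)]
  expected <- cor(ut(t(neural)), ut(t(behaviour_dissimilarity)))
  expect_equal(res$samples[1, 1], expected, tolerance = 1e-12)

  spear <- target_dsm_corr_measure(
    ds, list(target_dsm = behaviour_dissimilarity,
             corr_type = "spearman"))
  expected_sp <- cor(ut(t(neural)), ut(t(behaviour_dissimilarity)),
                     method = "spearman")
  expect_equal(spear$samples[1, 1], expected_sp, tolerance = 1e-12)

  expect_error(target_dsm_corr_measure(
    ds, list(target_dsm = behaviour_dissimilarity[1:5, 1:5])), "5x5")
  asym <- behaviour_dissimilarity
  asym[1, 2] <- 9
  expect_error(target_dsm_corr_measure(ds, list(target_dsm = asym)),
               "symmetric")
})

test_that("dissimilarity measure emits the upper triangle in pair order", {
  set.seed(24)
  x <- matrix(rnorm(3 * 10), 3)
  ds <- mvpa_dataset(x, targets = 1:3, chunks = c(1, 1, 1))
  res <- dissimilarity_matrix_measure(ds)
  expect_equal(dim(res$samples), c(3, 1))
  expect_identical(res$sa$dsm_row, c(1L, 1L, 2L))
  expect_identical(res$sa$dsm_col, c(2L, 3L, 3L))

  dup <- mvpa_dataset(x[c(1, 1, 2), ], targets = 1:3, chunks = rep(1, 3))
  dres <- dissimilarity_matrix_measure(dup)
  expect_equal(dres$samples[1, 1], 0)

  # unflatten along samples gives the square matrix (upper triangle)
  res5 <- dissimilarity_matrix_measure(
    mvpa_dataset(matrix(rnorm(5 * 8), 5), targets = 1:5,
                 chunks = rep(1, 5)))
  uf <- unflatten_dataset(res5, "samples", fill = 0)
  sq <- uf$array[, , 1]
  expect_equal(dim(sq), c(5, 5))
  full <- sq + t(sq)
  expect_equal(full, t(full))
  expect_true(all(diag(full) == 0))
  expect_equal(sq[1, 2], res5$samples[1, 1])

  expect_error(dissimilarity_matrix_measure(ds, list(metric = "nope")),
               "unknown metric")
})

test_that("time generalization scores every train/test time pair", {
  # time-constant, perfectly separable patterns: accuracy 1 everywhere
  set.seed(25)
  n_time <- 5
  n_chan <- 4
  patterns <- matrix(c(3, 0, 0, 3, 3, 3, 0, 0), 2, n_chan, byrow = TRUE)
  build_rows <- function(chunk) {
    per_time <- lapply(seq_len(n_time), function(t) {
      mvpa_dataset(patterns + matrix(rnorm(2 * n_chan, sd = 1e-3), 2),
                   sa = data.frame(targets = 1:2,
                                   chunks = rep(chunk, 2),
                                   time = rep(t, 2L)))
    })
    stack_datasets(per_time, "samples")
  }
  ds <- stack_datasets(list(build_rows(1), build_rows(2)), "samples")
  ds$sa$time <- as.integer(ds$sa$time)
  ds$a$sdim <- dim_list("time", list(seq(0, 0.4, 0.1)))
  expect_identical(validate_dataset(ds), character(0))

  res <- dim_generalization_measure(
    ds, list(dimension = "time", radius = 0,
             classifier = classify_lda))
  expect_equal(dim(res$samples), c(25, 1))
  expect_identical(res$a$sdim$labels, c("train_time", "test_time"))
  expect_identical(res$sa$train_time, rep(1:5, 5))
  expect_identical(res$sa$test_time, rep(1:5, each = 5))
  expect_true(all(res$samples[, 1] == 1))

  # oracle: brute-force double loop with manual slicing (radius 0)
  set.seed(26)
  noisy <- ds
  noisy$samples <- noisy$samples + matrix(rnorm(length(noisy$samples)),
                                          nrow(noisy$samples))
  got <- dim_generalization_measure(
    noisy, list(dimension = "time", radius = 0,
                classifier = classify_lda))
  for (probe in list(c(1, 1), c(2, 5), c(4, 3))) {
    tr <- which(noisy$sa$chunks == 1 & noisy$sa$time == probe[1])
    te <- which(noisy$sa$chunks == 2 & noisy$sa$time == probe[2])
    pred <- classify_lda(noisy$samples[tr, ], noisy$sa$targets[tr],
                         noisy$samples[te, ])
    acc <- mean(pred == noisy$sa$targets[te])
    row <- which(got$sa$train_time == probe[1] &
                   got$sa$test_time == probe[2])
    expect_equal(got$samples[row, 1], acc)
  }

  # radius 1 widens the feature window; still one row per pair
  wide <- dim_generalization_measure(
    noisy, list(dimension = "time", radius = 1,
                classifier = classify_lda))
  expect_equal(nrow(wide$samples), 25)

  bad <- ds
  bad$sa$chunks[1] <- 3L
  expect_error(dim_generalization_measure(
    bad, list(dimension = "time")), "chunks must be")
  expect_error(dim_generalization_measure(ds, list(dimension = "chan")),
               "not a sample dimension")
})

test_that("measure outputs satisfy the single-column contract", {
  ds <- make_tiny_ds(n_targets = 3, n_chunks = 4, seed = 27)
  results <- list(
    crossvalidation_measure(ds, list()),
    correlation_measure(ds),
    dissimilarity_matrix_measure(ds)
  )
  for (res in results) {
    expect_equal(ncol(res$samples), 1)
    expect_identical(validate_dataset(res), character(0))
  }
})

test_that("split-half correlation is centered at zero under pure noise", {
  values <- vapply(1:200, function(s) {
    ds <- make_tiny_ds(n_targets = 2, n_chunks = 4, effect = 0,
                       n_features = 20, seed = 1000 + s)
    correlation_measure(ds)$samples[1, 1]
  }, numeric(1))
  expect_gt(t.test(values)$p.value, 0.001)
})
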