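# measures all return a dataset whose samples matrix has exactly one column

measure_result <- function(samples, sa = NULL, a = NULL) {
  samples <- matrix(as.numeric(samples), ncol = 1)
  mvpa_dataset(samples, sa = sa, fa = data.frame(row.names = 1), a = a)
}

#' Cross-validated classification measure
#'
#' For every fold of the partition scheme, trains the classifier on the
#' training samples and predicts the test samples. With
#' \code{output = "accuracy"} the result is a single value: correct
#' predictions divided by total test predictions, pooled over folds (robust
#' to unequal fold sizes). With \code{output = "predictions"} the result
#' has one row per input sample holding its predicted target (from the last
#' fold that tested it; standard schemes test each sample once) with
#' \code{sa$targets} carried over, NA for samples never tested.
#'
#' If \code{opt$normalization} is set (\code{"demean"} or \code{"zscore"}),
#' normalization parameters are estimated on each training set and applied
#' to the corresponding test set.
#'
#' @param ds an \code{mvpa_dataset} with \code{sa$targets}.
#' @param opt list of options: \code{classifier} (uniform-signature
#'   function, default \code{\link{classify_lda}}), \code{partitions}
#'   (an \code{mvpa_partitions}; default nfold over chunks),
#'   \code{output}, \code{normalization}, plus options passed through to
#'   the classifier.
#' @return a single-column \code{mvpa_dataset}.
#' @export
crossvalidation_measure <- function(ds, opt = list()) {
  classifier <- if (is.null(opt$classifier)) classify_lda else opt$classifier
  partitions <- if (is.null(opt$partitions)) {
    make_partitions(ds, "nfold")
  } else {
    opt$partitions
  }
  output <- if (is.null(opt$output)) "accuracy" else opt$output
  violations <- check_partitions(partitions, ds)
  if (length(violations) > 0) {
    stop("invalid partitions:\n  ", paste(violations, collapse = "\n  "),
         call. = FALSE)
  }
  targets <- ds$sa$targets
  n <- nrow(ds$samples)
  predicted <- rep(NA_integer_, n)
  n_correct <- 0
  n_total <- 0
  for (fi in seq_along(partitions$folds)) {
    fold <- partitions$folds[[fi]]
    train_x <- ds$samples[fold$train, , drop = FALSE]
    test_x <- ds$samples[fold$test, , drop = FALSE]
    if (!is.null(opt$normalization)) {
      train_ds <- mvpa_dataset(train_x)
      norm <- normalize_dataset(train_ds, method = opt$normalization,
                                axis = "samples")
      train_x <- norm$ds$samples
      test_x <- normalize_dataset(mvpa_dataset(test_x),
                                  params = norm$params)$ds$samples
      keep <- colSums(!is.finite(train_x)) == 0
      train_x <- train_x[, keep, drop = FALSE]
      test_x <- test_x[, keep, drop = FALSE]
    }
    pred <- tryCatch(
      classifier(train_x, targets[fold$train], test_x, opt),
      error = function(e) stop(sprintf("fold %d: %s", fi,
                                       conditionMessage(e)),
                               call. = FALSE))
    predicted[fold$test] <- pred
    n_correct <- n_correct + sum(pred == targets[fold$test])
    n_total <- n_total + length(fold$test)
  }
  if (output == "accuracy") {
    measure_result(n_correct / n_total,
                   sa = data.frame(labels = "accuracy",
                                   stringsAsFactors = FALSE))
  } else if (output == "predictions") {
    measure_result(predicted,
                   sa = data.frame(targets = targets))
  } else {
    stop("unknown output option: ", output, call. = FALSE)
  }
}

clamped_atanh <- function(r) {
  lim <- 1 - 1e-15
  if (any(abs(r) > lim, na.rm = TRUE)) {
    warning("correlations with |r| ~ 1 clamped before Fisher transform",
            call. = FALSE)
    r <- pmin(pmax(r, -lim), lim)
  }
  atanh(r)
}

#' Split-half correlation measure
#'
#' Splits the samples into two halves (by \code{opt$split}, or the two
#' chunk values if there are exactly two, or \code{\link{chunkize}} into
#' two groups otherwise), computes per-target mean patterns in each half
#' and the target-by-target Pearson correlation matrix between the halves,
#' Fisher-transforms it, and contrasts on- versus off-diagonal values: the
#' default weight matrix has 1/C on the diagonal and -1/(C(C-1)) off it,
#' i.e. mean within-condition minus mean between-condition correlation.
#' The result is averaged over both half orderings. Positive values mean
#' patterns are more similar within than between conditions.
#'
#' @param ds an \code{mvpa_dataset} with \code{sa$targets} and
#'   \code{sa$chunks}; every target must occur in both halves.
#' @param opt list: \code{split} (optional integer vector of 1s and 2s
#'   assigning samples to halves), \code{weights} (optional C x C contrast
#'   matrix replacing the default).
#' @return a 1 x 1 \code{mvpa_dataset}.
#' @export
correlation_measure <- function(ds, opt = list()) {
  targets <- ds$sa$targets
  if (is.null(targets)) {
    stop("correlation_measure requires sa$targets", call. = FALSE)
  }
  half <- opt$split
  if (is.null(half)) {
    u <- unique(ds$sa$chunks)
    if (length(u) == 2) {
      half <- match(ds$sa$chunks, sort(u))
    } else {
      half <- chunkize(ds, 2)
    }
  }
  u_targets <- sort(unique(targets))
  nc <- length(u_targets)
  mean_patterns <- function(h) {
    m <- matrix(NA_real_, nc, ncol(ds$samples))
    for (ti in seq_len(nc)) {
      rows <- which(half == h & targets == u_targets[ti])
      if (length(rows) == 0) {
        stop(sprintf("target %s missing from half %d", u_targets[ti], h),
             call. = FALSE)
      }
      m[ti, ] <- colMeans(ds$samples[rows, , drop = FALSE])
    }
    m
  }
  m1 <- mean_patterns(1)
  m2 <- mean_patterns(2)
  w <- opt$weights
  if (is.null(w)) {
    w <- matrix(-1 / (nc * (nc - 1)), nc, nc)
    diag(w) <- 1 / nc
  }
  c12 <- stats::cor(t(m1), t(m2))
  z12 <- clamped_atanh(c12)
  value <- (sum(w * z12) + sum(w * t(z12))) / 2
  measure_result(value,
                 sa = data.frame(labels = "corr", stringsAsFactors = FALSE))
}

dsm_from_samples <- function(samples, metric = "correlation") {
  if (metric == "correlation") {
    1 - stats::cor(t(samples))
  } else if (metric == "euclidean") {
    as.matrix(stats::dist(samples))
  } else {
    stop("unknown metric: ", metric, call. = FALSE)
  }
}

upper_tri_vector <- function(m) {
  t(m)[lower.tri(t(m))]   # row-major upper triangle: (1,2),(1,3),...,(2,3)..
}

#' Representational similarity to a target dissimilarity matrix
#'
#' Computes the neural dissimilarity matrix between the sample rows (one
#' row per condition; default metric one minus Pearson correlation) and
#' returns the correlation between the upper-triangle vectors of the
#' neural and target matrices.
#'
#' @param ds an \code{mvpa_dataset} with one sample per condition (n >= 3).
#' @param opt list: \code{target_dsm} (n x n symmetric matrix, or its
#'   upper-triangle vector), \code{metric} (\code{"correlation"} or
#'   \code{"euclidean"}), \code{corr_type} (\code{"pearson"} or
#'   \code{"spearman"}).
#' @return a 1 x 1 \code{mvpa_dataset}.
#' @export
target_dsm_corr_measure <- function(ds, opt = list()) {
  n <- nrow(ds$samples)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  target <- opt$target_dsm
  if (is.null(target)) stop("opt$target_dsm is required", call. = FALSE)
  if (is.matrix(target)) {
    if (nrow(target) != n || ncol(target) != n) {
      stop(sprintf("target_dsm is %dx%d but dataset has %d samples",
                   nrow(target), ncol(target), n), call. = FALSE)
    }
    if (max(abs(target - t(target))) > 1e-8) {
      stop("target_dsm must be symmetric", call. = FALSE)
    }
    target_vec <- upper_tri_vector(target)
  } else {
    if (length(target) != n * (n - 1) / 2) {
      stop("target_dsm vector length does not match sample count",
           call. = FALSE)
    }
    target_vec <- as.numeric(target)
  }
  metric <- if (is.null(opt$metric)) "correlation" else opt$metric
  corr_type <- if (is.null(opt$corr_type)) "pearson" else opt$corr_type
  neural_vec <- upper_tri_vector(dsm_from_samples(ds$samples, metric))
  value <- stats::cor(neural_vec, target_vec, method = corr_type)
  measure_result(value,
                 sa = data.frame(labels = "rho", stringsAsFactors = FALSE))
}

#' Pairwise dissimilarity matrix measure
#'
#' Returns the upper triangle of the sample-by-sample dissimilarity matrix
#' as a column, in row-major pair order (1,2),(1,3),...,(1,n),(2,3),...
#' \code{sa} columns \code{dsm_row}/\code{dsm_col} give the two condition
#' indices per row and \code{a$sdim} describes the square structure, so
#' \code{\link{unflatten_dataset}} along samples yields the square matrix.
#'
#' @param ds an \code{mvpa_dataset} with n >= 2 samples.
#' @param opt list: \code{metric} (\code{"correlation"}, the default, or
#'   \code{"euclidean"}).
#' @return an n(n-1)/2 x 1 \code{mvpa_dataset}.
#' @export
dissimilarity_matrix_measure <- function(ds, opt = list()) {
  n <- nrow(ds$samples)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  metric <- if (is.null(opt$metric)) "correlation" else opt$metric
  dsm <- dsm_from_samples(ds$samples, metric)
  pairs <- which(upper.tri(dsm), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  cond <- seq_len(n)   # sample index; targets may repeat across samples
  sa <- data.frame(dsm_row = as.integer(pairs[, 1]),
                   dsm_col = as.integer(pairs[, 2]))
  a <- list(sdim = dim_list(c("dsm_row", "dsm_col"), list(cond, cond)))
  measure_result(dsm[pairs], sa = sa, a = a)
}

#' Generalization across a sample dimension (time generalization)
#'
#' For every pair of positions (t_train, t_test) along a sample dimension
#' (typically \code{time}, moved to the sample axis with
#' \code{\link{dim_transpose}}), builds a training set from the chunk-1
#' samples in a window of \code{radius} positions around t_train and a test
#' set from the chunk-2 samples around t_test (window positions become
#' additional features), and applies the inner measure with a single
#' train-to-test fold. Near the boundaries both windows are restricted to
#' the offsets valid for the two centers jointly, keeping the train and
#' test feature spaces aligned.
#'
#' @param ds an \code{mvpa_dataset} with the generalization dimension in
#'   \code{a$sdim} and \code{sa$chunks} of 1 (train) or 2 (test).
#' @param opt list: \code{dimension} (sdim label), \code{radius}
#'   (default 0), \code{measure} (inner measure, default
#'   \code{\link{crossvalidation_measure}}) and any inner-measure options
#'   such as \code{classifier}.
#' @return an \code{mvpa_dataset} with one column and
#'   n_train_positions x n_test_positions rows; \code{a$sdim} has labels
#'   \code{train_<dimension>} and \code{test_<dimension>} (train varying
#'   fastest).
#' @export
dim_generalization_measure <- function(ds, opt = list()) {
  dimension <- opt$dimension
  if (is.null(dimension)) stop("opt$dimension is required", call. = FALSE)
  if (is.null(ds$a$sdim) || !dimension %in% ds$a$sdim$labels) {
    stop(sprintf("'%s' is not a sample dimension (use dim_transpose first)",
                 dimension), call. = FALSE)
  }
  chunks <- ds$sa$chunks
  if (is.null(chunks) || !all(chunks %in% c(1, 2))) {
    stop("chunks must be 1 (train) or 2 (test)", call. = FALSE)
  }
  radius <- if (is.null(opt$radius)) 0 else opt$radius
  inner <- if (is.null(opt$measure)) crossvalidation_measure else opt$measure
  vals <- ds$a$sdim$values[[match(dimension, ds$a$sdim$labels)]]
  npos <- length(vals)
  pos <- ds$sa[[dimension]]
  targets <- ds$sa$targets

  # rows of each chunk at each position, in original order (base order)
  rows_at <- function(ch, p) which(chunks == ch & pos == p)
  inner_opt <- opt
  inner_opt$measure <- NULL
  inner_opt$dimension <- NULL
  inner_opt$radius <- NULL
  inner_opt$output <- "accuracy"

  values <- matrix(NA_real_, npos, npos)   # [train, test]
  for (t_test in seq_len(npos)) {
    for (t_train in seq_len(npos)) {
      offsets <- (-radius):radius
      offsets <- offsets[t_train + offsets >= 1 & t_train + offsets <= npos &
                         t_test + offsets >= 1 & t_test + offsets <= npos]
      collect <- function(ch, center) {
        blocks <- lapply(offsets, function(o) {
          idx <- rows_at(ch, center + o)
          ds$samples[idx, , drop = FALSE]
        })
        tg <- targets[rows_at(ch, center + offsets[1])]
        counts <- vapply(blocks, nrow, integer(1))
        if (length(unique(counts)) != 1) {
          stop("dataset is not dense along the generalization dimension",
               call. = FALSE)
        }
        list(x = do.call(cbind, blocks), targets = tg)
      }
      train <- collect(1, t_train)
      test <- collect(2, t_test)
      sub <- mvpa_dataset(rbind(train$x, test$x),
                          targets = c(train$targets, test$targets),
                          chunks = rep(c(1L, 2L),
                                       c(length(train$targets),
                                         length(test$targets))))
      fold <- list(train = seq_along(train$targets),
                   test = length(train$targets) + seq_along(test$targets))
      inner_opt$partitions <- structure(list(folds = list(fold)),
                                        class = "mvpa_partitions")
      res <- inner(sub, inner_opt)
      values[t_train, t_test] <- res$samples[1, 1]
    }
  }
  train_lab <- paste0("train_", dimension)
  test_lab <- paste0("test_", dimension)
  grid <- index_grid(c(npos, npos))
  sa <- data.frame(grid[[1]], grid[[2]])
  names(sa) <- c(train_lab, test_lab)
  a <- list(sdim = dim_list(c(train_lab, test_lab), list(vals, vals)))
  measure_result(as.vector(values), sa = sa, a = a)
}
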