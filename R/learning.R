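check_classifier_input <- function(samples_train, targets_train,
                                   samples_test) {
  if (anyNA(samples_train) || anyNA(samples_test) ||
      !all(is.finite(samples_train)) || !all(is.finite(samples_test))) {
    stop("classifier input contains non-finite values", call. = FALSE)
  }
  classes <- sort(unique(targets_train))
  if (length(classes) < 2) {
    stop("training set has fewer than 2 classes", call. = FALSE)
  }
  classes
}

#' Linear discriminant analysis classifier
#'
#' Fits class means and a regularized pooled within-class covariance
#' \eqn{\Sigma_r = \Sigma + \lambda (tr(\Sigma)/p) I} (with \eqn{\Sigma}
#' the pooled covariance using n - C degrees of freedom) and predicts by
#' the linear discriminant \eqn{\mu_c' \Sigma_r^{-1} x - \frac12 \mu_c'
#' \Sigma_r^{-1} \mu_c} under equal class priors. The trace scaling keeps
#' \eqn{\Sigma_r} invertible when features outnumber training samples, as
#' is typical inside searchlights. Ties go to the smallest class label.
#'
#' All classifiers in the package share this signature, so they are
#' interchangeable inside \code{\link{crossvalidation_measure}}.
#'
#' @param samples_train numeric matrix (n_train x p).
#' @param targets_train integer class labels (length n_train).
#' @param samples_test numeric matrix (n_test x p).
#' @param opt list of options; \code{regularization} is \eqn{\lambda}
#'   (default 0.01).
#' @return integer vector of predicted targets (length n_test).
#' @export
classify_lda <- function(samples_train, targets_train, samples_test,
                         opt = list()) {
  samples_train <- as.matrix(samples_train)
  samples_test <- as.matrix(samples_test)
  classes <- check_classifier_input(samples_train, targets_train,
                                    samples_test)
  lambda <- if (is.null(opt$regularization)) 0.01 else opt$regularization
  p <- ncol(samples_train)
  n <- nrow(samples_train)
  nc <- length(classes)
  mu <- matrix(0, nc, p)
  sigma <- matrix(0, p, p)
  for (ci in seq_len(nc)) {
    rows <- samples_train[targets_train == classes[ci], , drop = FALSE]
    mu[ci, ] <- colMeans(rows)
    centered <- sweep(rows, 2, mu[ci, ], "-")
    sigma <- sigma + crossprod(centered)
  }
  # with one sample per class the pooled estimate is undefined; the ridge
  # below then reduces the rule to nearest class mean
  sigma <- sigma / max(n - nc, 1L)
  scale <- sum(diag(sigma)) / p
  if (!is.finite(scale) || scale <= 0) scale <- 1
  sigma_r <- sigma + diag(lambda * scale, p)
  w <- solve(sigma_r, t(mu))                    # p x C
  bias <- -0.5 * colSums(t(mu) * w)             # -1/2 mu' S^-1 mu
  scores <- samples_test %*% w + rep(bias, each = nrow(samples_test))
  classes[max.col(scores, ties.method = "first")]
}

#' Gaussian naive Bayes classifier
#'
#' Models each feature within each class as an independent Gaussian (with
#' a variance floor of 1e-12 so constant features do not break the fit) and
#' predicts the class maximizing log prior plus summed log densities.
#' Priors are the empirical training class frequencies. Ties go to the
#' smallest class label.
#'
#' @inheritParams classify_lda
#' @return integer vector of predicted targets.
#' @export
classify_naive_bayes <- function(samples_train, targets_train,
                                 samples_test, opt = list()) {
  samples_train <- as.matrix(samples_train)
  samples_test <- as.matrix(samples_test)
  classes <- check_classifier_input(samples_train, targets_train,
                                    samples_test)
  var_floor <- 1e-12
  nc <- length(classes)
  n <- nrow(samples_train)
  scores <- matrix(0, nrow(samples_test), nc)
  for (ci in seq_len(nc)) {
    rows <- samples_train[targets_train == classes[ci], , drop = FALSE]
    mu <- colMeans(rows)
    v <- apply(rows, 2, stats::var)
    v[is.na(v) | v < var_floor] <- var_floor
    log_prior <- log(nrow(rows) / n)
    ll <- vapply(seq_len(nrow(samples_test)), function(t) {
      sum(stats::dnorm(samples_test[t, ], mu, sqrt(v), log = TRUE))
    }, numeric(1))
    scores[, ci] <- log_prior + ll
  }
  classes[max.col(scores, ties.method = "first")]
}

#' Support vector machine classifier (adapter)
#'
#' Thin adapter with the uniform classifier signature around
#' \code{e1071::svm} (linear kernel by default). Requires the optional
#' e1071 package.
#'
#' @inheritParams classify_lda
#' @return integer vector of predicted targets.
#' @export
classify_svm <- function(samples_train, targets_train, samples_test,
                         opt = list()) {
  if (!requireNamespace("e1071", quietly = TRUE)) {
    stop("classify_svm requires the e1071 package", call. = FALSE)
  }
  check_classifier_input(samples_train, targets_train, samples_test)
  kernel <- if (is.null(opt$kernel)) "linear" else opt$kernel
  fit <- e1071::svm(as.matrix(samples_train), factor(targets_train),
                    kernel = kernel,
                    cost = if (is.null(opt$cost)) 1 else opt$cost)
  as.integer(as.character(predict(fit, as.matrix(samples_test))))
}

#' Generate cross-validation partitions
#'
#' Builds train/test folds from the chunk structure. Schemes:
#' \describe{
#'   \item{nfold}{one fold per unique chunk; that chunk is the test set
#'     and all others the training set (leave-one-chunk-out).}
#'   \item{oddeven}{two folds splitting chunks by odd/even rank of the
#'     sorted unique chunk values.}
#'   \item{take_k_out}{one fold per k-combination of chunks; the
#'     combination is the test set.}
#'   \item{cross_grouped}{cross-decoding over a grouping attribute (e.g.
#'     modality or participant): for every ordered pair of distinct group
#'     values (train group, test group) and every chunk c, training
#'     samples are those of the train group with chunk != c and test
#'     samples those of the test group with chunk == c.}
#' }
#' Folds are ordered deterministically (sorted chunk/group values).
#'
#' @param ds an \code{mvpa_dataset} with \code{sa$chunks}.
#' @param scheme one of \code{"nfold"}, \code{"oddeven"},
#'   \code{"take_k_out"}, \code{"cross_grouped"}.
#' @param k number of chunks left out per fold (take_k_out only).
#' @param group name of the \code{sa} attribute holding the group values
#'   (cross_grouped only).
#' @return an object of class \code{mvpa_partitions}: a list with element
#'   \code{folds}, each fold a list with integer vectors \code{train} and
#'   \code{test}.
#' @export
make_partitions <- function(ds, scheme = c("nfold", "oddeven",
                                           "take_k_out", "cross_grouped"),
                            k = 1, group = NULL) {
  scheme <- match.arg(scheme)
  chunks <- ds$sa$chunks
  if (is.null(chunks)) {
    stop("make_partitions requires sa$chunks", call. = FALSE)
  }
  u <- sort(unique(chunks))
  if (length(u) < 2) {
    stop("need at least 2 unique chunks", call. = FALSE)
  }
  folds <- list()
  if (scheme == "nfold") {
    for (ch in u) {
      folds[[length(folds) + 1]] <-
        list(train = which(chunks != ch), test = which(chunks == ch))
    }
  } else if (scheme == "oddeven") {
    rank <- match(chunks, u)
    odd <- which(rank %% 2 == 1)
    even <- which(rank %% 2 == 0)
    folds <- list(list(train = odd, test = even),
                  list(train = even, test = odd))
  } else if (scheme == "take_k_out") {
    if (k < 1 || k >= length(u)) {
      stop(sprintf("k must be in 1..%d", length(u) - 1), call. = FALSE)
    }
    combos <- utils::combn(u, k, simplify = FALSE)
    for (cmb in combos) {
      folds[[length(folds) + 1]] <-
        list(train = which(!chunks %in% cmb),
             test = which(chunks %in% cmb))
    }
  } else {
    if (is.null(group) || is.null(ds$sa[[group]])) {
      stop("cross_grouped requires an existing sa group attribute",
           call. = FALSE)
    }
    gvals <- ds$sa[[group]]
    ug <- sort(unique(gvals))
    if (length(ug) < 2) {
      stop("cross_grouped requires at least 2 group values", call. = FALSE)
    }
    for (g_train in ug) {
      for (g_test in setdiff(ug, g_train)) {
        for (ch in u) {
          train <- which(gvals == g_train & chunks != ch)
          test <- which(gvals == g_test & chunks == ch)
          if (length(train) > 0 && length(test) > 0) {
            folds[[length(folds) + 1]] <- list(train = train, test = test)
          }
        }
      }
    }
  }
  structure(list(folds = folds), class = "mvpa_partitions")
}

#' @export
print.mvpa_partitions <- function(x, ...) {
  cat(sprintf("mvpa_partitions: %d folds\n", length(x$folds)))
  invisible(x)
}

#' Check partitions against a dataset
#'
#' Flags, per fold: train/test sample overlap, chunks present on both
#' sides, and target classes missing from the training set. Returns
#' descriptions rather than raising, mirroring
#' \code{\link{validate_dataset}}.
#'
#' @param partitions an \code{mvpa_partitions} object.
#' @param ds the \code{mvpa_dataset} the partitions refer to.
#' @return character vector of violation descriptions (empty if none).
#' @export
check_partitions <- function(partitions, ds) {
  out <- character(0)
  n <- nrow(ds$samples)
  all_targets <- sort(unique(ds$sa$targets))
  for (fi in seq_along(partitions$folds)) {
    fold <- partitions$folds[[fi]]
    if (any(fold$train < 1 | fold$train > n) ||
        any(fold$test < 1 | fold$test > n)) {
      out <- c(out, sprintf("fold %d: sample index out of range", fi))
      next
    }
    if (length(intersect(fold$train, fold$test)) > 0) {
      out <- c(out, sprintf("fold %d: train and test samples overlap", fi))
    }
    if (!is.null(ds$sa$chunks)) {
      shared <- intersect(ds$sa$chunks[fold$train],
                          ds$sa$chunks[fold$test])
      if (length(shared) > 0) {
        out <- c(out, sprintf("fold %d: chunk(s) %s in both train and test",
                              fi, paste(shared, collapse = ",")))
      }
    }
    if (!is.null(ds$sa$targets)) {
      miss <- setdiff(all_targets, ds$sa$targets[fold$train])
      if (length(miss) > 0) {
        out <- c(out, sprintf("fold %d: class(es) %s missing from training",
                              fi, paste(miss, collapse = ",")))
      }
    }
  }
  out
}
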