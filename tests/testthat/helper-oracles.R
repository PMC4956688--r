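# independent brute-force implementations used as oracles; deliberately
# written with plain loops, not sharing code with the package internals

# LDA: same discriminant, computed via per-class covariance sums and an
# explicit per-sample score loop
oracle_lda <- function(xtr, ytr, xte, lambda = 0.01) {
  classes <- sort(unique(ytr))
  p <- ncol(xtr)
  mus <- lapply(classes, function(cl) colMeans(xtr[ytr == cl, , drop = FALSE]))
  s <- matrix(0, p, p)
  for (ci in seq_along(classes)) {
    rows <- which(ytr == classes[ci])
    for (r in rows) {
      d <- xtr[r, ] - mus[[ci]]
      s <- s + outer(d, d)
    }
  }
  s <- s / (nrow(xtr) - length(classes))
  sr <- s + diag(lambda * mean(diag(s)), p)
  sri <- solve(sr)
  pred <- integer(nrow(xte))
  for (t in seq_len(nrow(xte))) {
    scores <- sapply(seq_along(classes), function(ci) {
      mu <- mus[[ci]]
      drop(mu %*% sri %*% xte[t, ] - 0.5 * mu %*% sri %*% mu)
    })
    pred[t] <- classes[which.max(scores)]
  }
  pred
}

# naive Bayes: explicit log-density sums per class/feature
oracle_naive_bayes <- function(xtr, ytr, xte, var_floor = 1e-12) {
  classes <- sort(unique(ytr))
  pred <- integer(nrow(xte))
  for (t in seq_len(nrow(xte))) {
    scores <- vapply(classes, function(cl) {
      rows <- xtr[ytr == cl, , drop = FALSE]
      ll <- log(nrow(rows) / nrow(xtr))
      for (f in seq_len(ncol(xtr))) {
        mu <- mean(rows[, f])
        v <- stats::var(rows[, f])
        if (is.na(v) || v < var_floor) v <- var_floor
        ll <- ll - 0.5 * log(2 * pi * v) - (xte[t, f] - mu)^2 / (2 * v)
      }
      ll
    }, numeric(1))
    pred[t] <- classes[which.max(scores)]
  }
  pred
}

# flood-fill connected components in plain R (independent of the compiled
# labeling); returns list of clusters of {map >= threshold}
oracle_clusters <- function(map, threshold, neighbors) {
  n <- length(map)
  supra <- map >= threshold
  seen <- rep(FALSE, n)
  clusters <- list()
  for (f in seq_len(n)) {
    if (!supra[f] || seen[f]) next
    comp <- integer(0)
    queue <- f
    seen[f] <- TRUE
    while (length(queue) > 0) {
      cur <- queue[1]
      queue <- queue[-1]
      comp <- c(comp, cur)
      for (g in neighbors[[cur]]) {
        if (supra[g] && !seen[g]) {
          seen[g] <- TRUE
          queue <- c(queue, g)
        }
      }
    }
    clusters[[length(clusters) + 1]] <- sort(comp)
  }
  clusters
}

# per-threshold-loop TFCE in plain R for non-negative maps
oracle_tfce <- function(map, neighbors, E = 0.5, H = 2, dh = 0.1) {
  out <- numeric(length(map))
  mx <- max(map)
  if (mx <= 0) return(out)
  for (step in seq_len(floor(mx / dh + 1e-9))) {
    h <- step * dh
    for (cl in oracle_clusters(map, h, neighbors)) {
      out[cl] <- out[cl] + length(cl)^E * h^H * dh
    }
  }
  out
}

signed_oracle_tfce <- function(map, neighbors, ...) {
  oracle_tfce(pmax(map, 0), neighbors, ...) -
    oracle_tfce(pmax(-map, 0), neighbors, ...)
}

# small dense channel-free dataset for structural tests
make_tiny_ds <- function(n_targets = 2, n_chunks = 4, n_features = 6,
                         effect = 2, seed = 42) {
  set.seed(seed)
  n <- n_targets * n_chunks
  targets <- rep(seq_len(n_targets), n_chunks)
  chunks <- rep(seq_len(n_chunks), each = n_targets)
  patterns <- matrix(rnorm(n_targets * n_features), n_targets) * effect
  samples <- patterns[targets, ] + matrix(rnorm(n * n_features), n)
  mvpa_dataset(samples, targets = targets, chunks = chunks)
}

expect_same_dataset <- function(a, b, tol = 0) {
  if (tol == 0) {
    expect_identical(unname(a$samples), unname(b$samples))
  } else {
    expect_equal(unname(a$samples), unname(b$samples), tolerance = tol)
  }
  expect_equal(as.list(a$sa), as.list(b$sa), ignore_attr = TRUE)
  expect_equal(as.list(a$fa), as.list(b$fa), ignore_attr = TRUE)
  expect_equal(a$a, b$a, ignore_attr = TRUE)
}
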