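# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Normalize a dataset
#'
#' Subtracts the mean (\code{demean}) or additionally divides by the sample
#' standard deviation (\code{zscore}, denominator n-1) along the chosen
#' axis. With \code{axis = "samples"} statistics are computed over samples,
#' i.e. each feature column is centered/scaled; with \code{axis =
#' "features"} each sample row is. The returned parameters can be passed
#' back via \code{params} to apply the identical transform to new data —
#' the standard pattern is estimating them on a training set and applying
#' them to a test set.
#'
#' Zero-variance entries under \code{zscore} produce \code{NaN} with a
#' warning rather than an error, so downstream masks can remove them.
#'
#' @param ds an \code{mvpa_dataset}.
#' @param method \code{"demean"} or \code{"zscore"}.
#' @param axis \code{"samples"} or \code{"features"}.
#' @param params optional parameter list from a previous call; when given,
#'   \code{method}/\code{axis} are taken from it.
#' @return list with elements \code{ds} (normalized dataset) and
#'   \code{params}.
#' @export
normalize_dataset <- function(ds, method = c("demean", "zscore"),
                              axis = c("samples", "features"),
                              params = NULL) {
  if (is.null(params)) {
    method <- match.arg(method)
    axis <- match.arg(axis)
    x <- if (axis == "samples") ds$samples else t(ds$samples)
    mu <- colMeans(x)
    sigma <- NULL
    if (method == "zscore") {
      sigma <- apply(x, 2, stats::sd)
      if (any(sigma == 0, na.rm = TRUE)) {
        warning("zero-variance entries produce NaN under zscore",
                call. = FALSE)
      }
      sigma[sigma == 0] <- NaN
    }
    params <- list(method = method, axis = axis, mean = mu, sd = sigma)
  } else {
    method <- params$method
    axis <- params$axis
  }
  n_expected <- if (axis == "samples") ncol(ds$samples) else nrow(ds$samples)
  if (length(params$mean) != n_expected) {
    stop(sprintf("params length %d does not match %d %s",
                 length(params$mean), n_expected,
                 if (axis == "samples") "features" else "samples"),
         call. = FALSE)
  }
  x <- if (axis == "samples") ds$samples else t(ds$samples)
  x <- sweep(x, 2, params$mean, "-")
  if (method == "zscore") {
    x <- sweep(x, 2, params$sd, "/")
  }
  ds$samples <- if (axis == "samples") x else t(x)
  list(ds = ds, params = params)
}

#' Re-assign chunks into a smaller number of balanced groups
#'
#' Deterministically maps the existing chunk values onto \code{1..nchunks}:
#' the unique chunk values are sorted ascending and dealt round-robin into
#' the output bins, so all samples sharing an original chunk stay together
#' and bin sizes (in original chunks) differ by at most one. Used e.g. to
#' derive the two halves for split-half correlation analysis.
#'
#' @param ds an \code{mvpa_dataset} with \code{sa$chunks} and
#'   \code{sa$targets}.
#' @param nchunks number of output chunk values.
#' @return integer vector of length n_samples with values in
#'   \code{1..nchunks}.
#' @export
chunkize <- function(ds, nchunks) {
  if (is.null(ds$sa$chunks) || is.null(ds$sa$targets)) {
    stop("chunkize requires sa$chunks and sa$targets", call. = FALSE)
  }
  u <- sort(unique(ds$sa$chunks))
  if (length(u) < nchunks) {
    stop(sprintf("cannot split %d unique chunks into %d groups",
                 length(u), nchunks), call. = FALSE)
  }
  bin <- ((seq_along(u) - 1L) %% as.integer(nchunks)) + 1L
  bin[match(ds$sa$chunks, u)]
}

#' Permute condition labels within chunks
#'
#' Randomly permutes \code{sa$targets} within each chunk, preserving the
#' per-chunk target histogram (and hence the chunk exchangeability
#' structure). Used to generate measure outcomes under the null hypothesis.
#'
#' @param ds an \code{mvpa_dataset} with \code{sa$targets} and
#'   \code{sa$chunks}.
#' @param seed integer seed; the same seed always yields the same
#'   permutation and the caller's RNG state is left untouched.
#' @return integer vector of permuted targets (length n_samples).
#' @export
randomize_targets <- function(ds, seed) {
  if (is.null(ds$sa$targets) || is.null(ds$sa$chunks)) {
    stop("randomize_targets requires sa$targets and sa$chunks",
         call. = FALSE)
  }
  targets <- ds$sa$targets
  chunks <- ds$sa$chunks
  with_seed(seed, {
    for (ch in sort(unique(chunks))) {
      idx <- which(chunks == ch)
      if (length(idx) > 1) {
        targets[idx] <- targets[idx][sample.int(length(idx))]
      }
    }
    targets
  })
}
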