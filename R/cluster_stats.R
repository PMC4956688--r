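#' Automatic feature adjacency from dataset dimensions
#'
#' Builds the neighborhood used for clustering directly from the dataset's
#' feature dimensions: two features are adjacent when they are adjacent in
#' every dimension group. Voxel dimensions \code{i,j,k} use 26-connectivity
#' (all index offsets of at most 1); time/frequency/positional dimensions
#' use an offset of at most \code{bin_radius} bins; a \code{chan} dimension
#' uses sensor locations within \code{chan_radius} layout units of each
#' other. Each feature is included in its own neighbor list.
#'
#' @param ds an \code{mvpa_dataset} with \code{a$fdim}.
#' @param layout an \code{mvpa_layout}; required when the dataset has a
#'   \code{chan} dimension.
#' @param chan_radius layout-unit radius for channel adjacency (default
#'   1.5, which connects immediate horizontal, vertical and diagonal
#'   neighbors on a unit grid).
#' @param bin_radius bin radius for time/frequency adjacency (default 1).
#' @return an \code{mvpa_neighborhood} whose output space equals the input
#'   space.
#' @export
feature_adjacency <- function(ds, layout = NULL, chan_radius = 1.5,
                              bin_radius = 1) {
  if (is.null(ds$a$fdim)) {
    stop("feature_adjacency requires a$fdim", call. = FALSE)
  }
  labels <- ds$a$fdim$labels
  nf <- ncol(ds$samples)
  ok <- matrix(TRUE, nf, nf)

  spatial <- intersect(c("i", "j", "k"), labels)
  for (lab in spatial) {
    idx <- ds$fa[[lab]]
    ok <- ok & (abs(outer(idx, idx, "-")) <= 1)
  }
  if ("chan" %in% labels) {
    if (is.null(layout)) {
      stop("a layout is required for channel adjacency", call. = FALSE)
    }
    chan_vals <- as.character(ds$a$fdim$values[[match("chan", labels)]])
    unknown <- setdiff(chan_vals, layout$channel)
    if (length(unknown) > 0) {
      stop("channels missing from layout: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    feat_chan <- chan_vals[ds$fa$chan]
    x <- layout$x[match(feat_chan, layout$channel)]
    y <- layout$y[match(feat_chan, layout$channel)]
    d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
    ok <- ok & (d2 <= chan_radius^2)
  }
  for (lab in setdiff(labels, c(spatial, "chan"))) {
    idx <- ds$fa[[lab]]
    ok <- ok & (abs(outer(idx, idx, "-")) <= bin_radius)
  }
  neighbors <- lapply(seq_len(nf), function(f) which(ok[f, ]))
  new_neighborhood(neighbors, fa = ds$fa, a = ds$a,
                   origin = neighborhood_origin(ds))
}

#' Threshold-free cluster enhancement
#'
#' Integrates cluster extent and height over all thresholds: for positive
#' map values, \eqn{TFCE(f) = \sum_{h = dh, 2dh, ...} e(f,h)^E h^H dh}
#' where \eqn{e(f,h)} is the number of features in the supra-threshold
#' (map >= h) connected component containing f. Negative values are
#' processed on the negated map and re-negated; zeros map to zero. This
#' removes the need to choose a single cluster-forming threshold.
#'
#' @param map finite numeric vector (one value per feature).
#' @param adjacency an \code{mvpa_neighborhood} over the same features
#'   (e.g. from \code{\link{feature_adjacency}}).
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh threshold step (default 0.1).
#' @return numeric vector of signed TFCE scores.
#' @export
tfce_transform <- function(map, adjacency, E = 0.5, H = 2, dh = 0.1) {
  if (!all(is.finite(map))) {
    stop("tfce_transform requires a finite map", call. = FALSE)
  }
  stopifnot(dh > 0)
  if (length(map) != length(adjacency$neighbors)) {
    stop("map length does not match adjacency", call. = FALSE)
  }
  pos <- .tfce_nonneg(pmax(map, 0), adjacency$neighbors, E, H, dh)
  neg <- .tfce_nonneg(pmax(-map, 0), adjacency$neighbors, E, H, dh)
  pos - neg
}

#' Find supra-threshold clusters
#'
#' Connected components of \code{map >= threshold} under the adjacency,
#' with the cluster mass (sum of supra-threshold values).
#'
#' @param map finite numeric vector.
#' @param threshold cluster-forming threshold.
#' @param adjacency an \code{mvpa_neighborhood} over the same features.
#' @return list with \code{clusters} (list of integer feature-index
#'   vectors) and \code{mass} (numeric vector of cluster masses).
#' @export
find_clusters <- function(map, threshold, adjacency) {
  if (!all(is.finite(map))) {
    stop("find_clusters requires a finite map", call. = FALSE)
  }
  labels <- .label_components(map, threshold, adjacency$neighbors)
  k <- max(labels)
  clusters <- lapply(seq_len(k), function(ci) which(labels == ci))
  mass <- vapply(clusters, function(cl) sum(map[cl]), numeric(1))
  list(clusters = clusters, mass = mass)
}

# one-sample t against h0_mean, columns of x; zero-variance columns give 0
# when the mean equals h0_mean and a capped +/- t otherwise
col_t_stat <- function(x, h0_mean, cap = 100) {
  n <- nrow(x)
  m <- colMeans(x)
  s2 <- (colSums(x^2) - n * m^2) / (n - 1)
  s2[s2 < 0] <- 0
  se <- sqrt(s2 / n)
  t <- (m - h0_mean) / se
  zero <- se == 0
  t[zero] <- sign(m[zero] - h0_mean) * cap
  pmin(pmax(t, -cap), cap)
}

# per-feature fixed-threshold cluster mass, signed
fixed_cluster_stat <- function(t_map, threshold, adjacency, tails) {
  stat_side <- function(m) {
    fc <- find_clusters(m, threshold, adjacency)
    out <- numeric(length(m))
    for (ci in seq_along(fc$clusters)) {
      out[fc$clusters[[ci]]] <- fc$mass[ci]
    }
    out
  }
  if (tails == 2) stat_side(t_map) - stat_side(-t_map) else stat_side(t_map)
}

#' Monte-Carlo cluster statistics at the group level
#'
#' Computes a feature-wise one-sample t statistic of the participant maps
#' against \code{h0_mean}, transforms it with TFCE (or fixed-threshold
#' cluster mass), and derives family-wise-error-corrected p-values from the
#' permutation distribution of the maximum statistic across features.
#' Null iterations either flip the sign of each participant's
#' (map - h0_mean) independently (\code{method = "sign_flip"}) or draw one
#' pre-computed null map per participant with replacement
#' (\code{method = "null_map_sampling"}, with null maps generated e.g. by
#' label permutation at the first level). Corrected p-values are
#' \eqn{(1 + \#\{max null stat \ge observed\})/(niter + 1)} and are
#' converted to signed z-scores.
#'
#' @param group_ds an \code{mvpa_dataset} with one sample (row) per
#'   participant.
#' @param adjacency an \code{mvpa_neighborhood} over the features (see
#'   \code{\link{feature_adjacency}}).
#' @param opt list of options:
#'   \describe{
#'     \item{niter}{number of null iterations (default 1000).}
#'     \item{h0_mean}{null-hypothesis mean (0 for correlations, chance
#'       level for accuracy maps; default 0).}
#'     \item{method}{\code{"sign_flip"} (default) or
#'       \code{"null_map_sampling"}.}
#'     \item{null_maps}{for null_map_sampling: list with one matrix of
#'       null maps (rows) per participant.}
#'     \item{cluster_stat}{\code{list(type = "tfce", E, H, dh)} (default)
#'       or \code{list(type = "fixed", threshold = t)}.}
#'     \item{tails}{1 or 2; default 1 when \code{h0_mean != 0} (accuracy
#'       against chance), 2 otherwise.}
#'     \item{seed}{RNG seed (default 0).}
#'   }
#' @return an object of class \code{mvpa_clusterstat}: list with \code{z}
#'   (1 x n_features dataset of signed z-scores), \code{p} (corrected
#'   p-values), \code{null_max} (per-iteration max statistics) and
#'   \code{params}.
#' @export
montecarlo_cluster_stat <- function(group_ds, adjacency, opt = list()) {
  x <- group_ds$samples
  if (nrow(x) < 2) stop("need at least 2 participants", call. = FALSE)
  if (!all(is.finite(x))) stop("group maps must be finite", call. = FALSE)
  niter <- if (is.null(opt$niter)) 1000L else as.integer(opt$niter)
  if (niter < 1) stop("niter must be >= 1", call. = FALSE)
  h0_mean <- if (is.null(opt$h0_mean)) 0 else opt$h0_mean
  method <- if (is.null(opt$method)) "sign_flip" else opt$method
  cs <- if (is.null(opt$cluster_stat)) list(type = "tfce")
        else opt$cluster_stat
  tails <- if (is.null(opt$tails)) (if (h0_mean != 0) 1 else 2)
           else opt$tails
  seed <- if (is.null(opt$seed)) 0L else opt$seed
  n_part <- nrow(x)

  if (method == "null_map_sampling") {
    nm <- opt$null_maps
    if (is.null(nm) || length(nm) != n_part ||
        any(vapply(nm, nrow, integer(1)) < 1)) {
      stop("null_map_sampling requires >= 1 null map per participant",
           call. = FALSE)
    }
  } else if (method != "sign_flip") {
    stop("unknown method: ", method, call. = FALSE)
  }

  stat_fun <- function(maps) {
    t_map <- col_t_stat(maps, h0_mean)
    if (identical(cs$type, "tfce")) {
      E <- if (is.null(cs$E)) 0.5 else cs$E
      H <- if (is.null(cs$H)) 2 else cs$H
      dh <- if (is.null(cs$dh)) 0.1 else cs$dh
      if (tails == 2) {
        tfce_transform(t_map, adjacency, E, H, dh)
      } else {
        .tfce_nonneg(pmax(t_map, 0), adjacency$neighbors, E, H, dh)
      }
    } else if (identical(cs$type, "fixed")) {
      if (is.null(cs$threshold)) {
        stop("fixed cluster_stat requires a threshold", call. = FALSE)
      }
      fixed_cluster_stat(t_map, cs$threshold, adjacency, tails)
    } else {
      stop("unknown cluster_stat type", call. = FALSE)
    }
  }
  observed <- stat_fun(x)
  centered <- x - h0_mean
  null_max <- with_seed(seed, {
    vapply(seq_len(niter), function(it) {
      maps <- if (method == "sign_flip") {
        signs <- sample(c(-1, 1), n_part, replace = TRUE)
        h0_mean + centered * signs
      } else {
        do.call(rbind, lapply(opt$null_maps, function(m) {
          m[sample.int(nrow(m), 1L), ]
        }))
      }
      s <- stat_fun(maps)
      if (tails == 2) max(abs(s)) else max(s)
    }, numeric(1))
  })
  obs_cmp <- if (tails == 2) abs(observed) else observed
  p <- (1 + vapply(obs_cmp, function(v) sum(null_max >= v),
                   numeric(1))) / (niter + 1)
  p <- pmin(pmax(p, 1 / (niter + 1)), niter / (niter + 1))
  z <- if (tails == 2) {
    sign(observed) * stats::qnorm(1 - p / 2)
  } else {
    stats::qnorm(1 - p)
  }
  z[observed == 0] <- 0
  z_ds <- mvpa_dataset(matrix(z, nrow = 1), fa = group_ds$fa,
                       a = group_ds$a)
  structure(list(z = z_ds, p = p, null_max = null_max,
                 params = list(niter = niter, seed = seed,
                               h0_mean = h0_mean, method = method,
                               cluster_stat = cs, tails = tails)),
            class = "mvpa_clusterstat")
}

#' @export
print.mvpa_clusterstat <- function(x, ...) {
  cat(sprintf(
    "mvpa_clusterstat: %d features, %d iterations (%s, %s, %d-tailed)\n",
    ncol(x$z$samples), x$params$niter, x$params$method,
    x$params$cluster_stat$type, x$params$tails))
  if (x$params$tails == 1) {
    cat(sprintf("  max z = %.3f; %d feature(s) with z > 1.96\n",
                max(x$z$samples), sum(x$z$samples > 1.96)))
  } else {
    cat(sprintf("  max |z| = %.3f; %d feature(s) with |z| > 1.96\n",
                max(abs(x$z$samples)), sum(abs(x$z$samples) > 1.96)))
  }
  invisible(x)
}
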