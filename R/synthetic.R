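#' Generate a toy M/EEG channel-by-time dataset
#'
#' Emulates a small time-locked planar-gradiometer recording: 18 planar
#' channels (9 sensor locations on a 3x3 grid, two gradiometers each) by
#' \code{n_time} time bins, with one sample per (target, chunk)
#' combination. Each condition has a fixed mean pattern, drawn once per
#' dataset and scaled by \code{effect_size}, injected on a subset of
#' channels and time bins on top of i.i.d. standard Gaussian noise;
#' \code{effect_size = 0} yields pure null data. Deterministic per seed.
#'
#' @param n_targets number of conditions (default 3).
#' @param n_chunks number of independence groups, e.g. runs (default 4).
#' @param layout layout name (default \code{"toy9"}).
#' @param n_time number of time bins (default 5).
#' @param t0 time of the first bin in seconds (default 0).
#' @param dt bin width in seconds (default 0.1).
#' @param effect_size standard deviation of the condition mean patterns,
#'   in noise-SD units (default 1).
#' @param signal_channels,signal_times indices of channels/time bins
#'   carrying signal (defaults: the 8 planar channels of the first four
#'   sensor locations; all but the first time bin).
#' @param seed RNG seed (default 1).
#' @return an \code{mvpa_dataset} with fdim \code{chan} x \code{time}.
#' @export
make_toy_meeg <- function(n_targets = 3, n_chunks = 4, layout = "toy9",
                          n_time = 5, t0 = 0, dt = 0.1, effect_size = 1,
                          signal_channels = NULL, signal_times = NULL,
                          seed = 1) {
  lay <- load_layout(layout)
  chan_names <- lay$channel[lay$kind %in% c("planar", "eeg")]
  n_chan <- length(chan_names)
  times <- t0 + dt * (seq_len(n_time) - 1)
  if (is.null(signal_channels)) {
    signal_channels <- seq_len(min(8, n_chan))
  }
  if (is.null(signal_times)) {
    signal_times <- if (n_time > 1) 2:n_time else 1L
  }
  n_samples <- n_targets * n_chunks
  nf <- n_chan * n_time
  sig_feat <- as.vector(outer(signal_channels,
                              (signal_times - 1) * n_chan, "+"))
  with_seed(seed, {
    patterns <- matrix(stats::rnorm(n_targets * length(sig_feat)),
                       n_targets) * effect_size
    samples <- matrix(stats::rnorm(n_samples * nf), n_samples, nf)
    targets <- rep(seq_len(n_targets), n_chunks)
    chunks <- rep(seq_len(n_chunks), each = n_targets)
    for (s in seq_len(n_samples)) {
      samples[s, sig_feat] <- samples[s, sig_feat] + patterns[targets[s], ]
    }
    grid <- index_grid(c(n_chan, n_time))
    names(grid) <- c("chan", "time")
    mvpa_dataset(samples, fa = grid,
                 a = list(fdim = dim_list(c("chan", "time"),
                                          list(chan_names, times))),
                 targets = targets, chunks = chunks)
  })
}

#' Generate a toy volumetric fMRI dataset
#'
#' A full-grid volumetric dataset with a diagonal affine (isotropic
#' \code{voxel_mm} voxels, voxel (1,1,1) at the world origin), one sample
#' per (target, chunk) combination, condition-specific mean patterns
#' inside \code{signal_region} and standard Gaussian noise everywhere.
#'
#' @param dim 3-element grid size (default \code{c(10, 10, 10)}).
#' @param voxel_mm isotropic voxel size in mm (default 3).
#' @param n_targets number of conditions (default 2).
#' @param n_chunks number of chunks/runs (default 4).
#' @param n_reps samples per condition within each chunk (default 4,
#'   as in a block design with four blocks per condition per run).
#' @param signal_region linear voxel indices (column-major) carrying
#'   signal; default a 3x3x3 block at grid positions 4..6 in each axis.
#' @param effect_size standard deviation of the condition mean patterns
#'   (default 1).
#' @param seed RNG seed (default 1).
#' @return an \code{mvpa_dataset} with fdim \code{i,j,k} and \code{a$vol}.
#' @export
make_toy_fmri <- function(dim = c(10, 10, 10), voxel_mm = 3,
                          n_targets = 2, n_chunks = 4, n_reps = 4,
                          signal_region = NULL, effect_size = 1,
                          seed = 1) {
  stopifnot(length(dim) == 3)
  nf <- prod(dim)
  if (is.null(signal_region)) {
    block <- lapply(dim, function(d) {
      lo <- min(4, d)
      hi <- min(6, d)
      lo:hi
    })
    g <- expand.grid(block)
    signal_region <- g[[1]] + dim[1] * (g[[2]] - 1) +
      dim[1] * dim[2] * (g[[3]] - 1)
  }
  if (any(signal_region < 1 | signal_region > nf)) {
    stop("signal_region outside the grid", call. = FALSE)
  }
  mat <- diag(c(rep(voxel_mm, 3), 1))
  mat[1:3, 4] <- -voxel_mm   # voxel (1,1,1) -> world (0,0,0)
  n_samples <- n_targets * n_chunks * n_reps
  with_seed(seed, {
    patterns <- matrix(stats::rnorm(n_targets * length(signal_region)),
                       n_targets) * effect_size
    samples <- matrix(stats::rnorm(n_samples * nf), n_samples, nf)
    targets <- rep(seq_len(n_targets), n_chunks * n_reps)
    chunks <- rep(seq_len(n_chunks), each = n_targets * n_reps)
    for (s in seq_len(n_samples)) {
      samples[s, signal_region] <- samples[s, signal_region] +
        patterns[targets[s], ]
    }
    grid <- index_grid(dim)
    names(grid) <- c("i", "j", "k")
    mvpa_dataset(samples, fa = grid,
                 a = list(fdim = dim_list(c("i", "j", "k"),
                                          lapply(dim, seq_len)),
                          vol = list(mat = mat, dim = as.integer(dim))),
                 targets = targets, chunks = chunks)
  })
}

#' Generate group-level participant maps
#'
#' One map (sample) per participant: \code{true_effect} plus i.i.d.
#' Gaussian noise with standard deviation \code{noise_sd}. Features carry
#' a 1-D positional dimension \code{pos} so that
#' \code{\link{feature_adjacency}} connects adjacent features. Chunks hold
#' the participant index and targets are all 1. Feeds
#' \code{\link{montecarlo_cluster_stat}}.
#'
#' @param n_participants number of participants (default 12).
#' @param n_features number of features (default 100).
#' @param true_effect scalar or length-\code{n_features} vector of true
#'   map values (default 0 for null data).
#' @param noise_sd noise standard deviation (default 1).
#' @param seed RNG seed (default 1).
#' @return an \code{mvpa_dataset}, participants x features.
#' @export
make_group_maps <- function(n_participants = 12, n_features = 100,
                            true_effect = 0, noise_sd = 1, seed = 1) {
  effect <- rep_len(true_effect, n_features)
  with_seed(seed, {
    samples <- matrix(stats::rnorm(n_participants * n_features,
                                   sd = noise_sd),
                      n_participants, n_features)
    samples <- sweep(samples, 2, effect, "+")
    mvpa_dataset(samples,
                 fa = data.frame(pos = seq_len(n_features)),
                 a = list(fdim = dim_list("pos", list(seq_len(n_features)))),
                 targets = rep(1L, n_participants),
                 chunks = seq_len(n_participants))
  })
}
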