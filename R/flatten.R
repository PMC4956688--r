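#' Flatten a multi-dimensional array into a dataset
#'
#' Converts a dense array into the two-dimensional samples representation,
#' generating the dimension index columns by enumeration of the dimension
#' grid. The first listed dimension varies fastest (column-major over the
#' listed dimension order), so flattening and unflattening are exact
#' inverses on dense data.
#'
#' @param array numeric array; for \code{axis = "features"} its shape is
#'   n_samples x d1 x ... x dk, for \code{axis = "samples"} it is
#'   d1 x ... x dk x n_features.
#' @param labels character vector of dimension names (length k).
#' @param values list of k coordinate-value vectors; \code{length(values[[i]])}
#'   must equal \code{di}.
#' @param axis which axis the dimensions describe.
#' @return an \code{mvpa_dataset} with \code{a$fdim} (or \code{a$sdim}) set
#'   and index columns in \code{fa} (or \code{sa}).
#' @seealso \code{\link{unflatten_dataset}}
#' @export
flatten_dataset <- function(array, labels, values,
                            axis = c("features", "samples")) {
  axis <- match.arg(axis)
  k <- length(labels)
  if (length(values) != k) {
    stop("labels and values must have equal length", call. = FALSE)
  }
  dims <- dim(array)
  if (is.null(dims)) dims <- length(array)
  dim_sizes <- vapply(values, length, integer(1))
  if (axis == "features") {
    if (length(dims) != k + 1 || !all(dims[-1] == dim_sizes)) {
      stop("array shape does not match the dimension value lists",
           call. = FALSE)
    }
    n <- dims[1]
    samples <- array
    dim(samples) <- c(n, prod(dim_sizes))
    grid <- index_grid(dim_sizes)
    names(grid) <- labels
    mvpa_dataset(samples, fa = grid,
                 a = list(fdim = dim_list(labels, values)))
  } else {
    if (length(dims) != k + 1 || !all(dims[seq_len(k)] == dim_sizes)) {
      stop("array shape does not match the dimension value lists",
           call. = FALSE)
    }
    nf <- dims[k + 1]
    samples <- array
    dim(samples) <- c(prod(dim_sizes), nf)
    grid <- index_grid(dim_sizes)
    names(grid) <- labels
    mvpa_dataset(samples, sa = grid,
                 a = list(sdim = dim_list(labels, values)))
  }
}

# all index combinations, first dimension fastest
index_grid <- function(dim_sizes) {
  g <- do.call(expand.grid, lapply(dim_sizes, seq_len))
  names(g) <- NULL
  as.data.frame(lapply(g, as.integer),
                col.names = paste0("d", seq_along(dim_sizes)))
}

# linear position (1-based, first label fastest) of each row/column in the
# dimension grid described by `dl` using index columns from `attrs`
grid_positions <- function(attrs, dl) {
  sizes <- vapply(dl$values, length, integer(1))
  pos <- rep(1L, nrow(attrs))
  stride <- 1L
  for (i in seq_along(dl$labels)) {
    idx <- attrs[[dl$labels[i]]]
    pos <- pos + (as.integer(idx) - 1L) * stride
    stride <- stride * sizes[i]
  }
  pos
}

#' Unflatten a dataset into a multi-dimensional array
#'
#' Places the samples into an array indexed by the dimension index columns;
#' grid positions absent from the dataset receive \code{fill}. The inverse
#' of \code{\link{flatten_dataset}} on dense datasets.
#'
#' @param ds an \code{mvpa_dataset} with \code{a$fdim} (features) or
#'   \code{a$sdim} (samples) present.
#' @param axis which axis to unflatten.
#' @param fill value for grid positions not present (default \code{NaN}).
#' @return list with elements \code{array}, \code{labels}, \code{values}.
#' @export
unflatten_dataset <- function(ds, axis = c("features", "samples"),
                              fill = NaN) {
  axis <- match.arg(axis)
  dl <- if (axis == "features") ds$a$fdim else ds$a$sdim
  if (is.null(dl)) {
    stop(sprintf("dataset has no %s to unflatten along %s",
                 if (axis == "features") "a$fdim" else "a$sdim", axis),
         call. = FALSE)
  }
  attrs <- if (axis == "features") ds$fa else ds$sa
  pos <- grid_positions(attrs, dl)
  if (anyDuplicated(pos)) {
    stop("duplicate grid position: two entries map to the same array cell",
         call. = FALSE)
  }
  sizes <- unname(vapply(dl$values, length, integer(1)))
  if (axis == "features") {
    n <- nrow(ds$samples)
    arr <- matrix(fill, n, prod(sizes))
    arr[, pos] <- ds$samples
    dim(arr) <- c(n, sizes)
  } else {
    nf <- ncol(ds$samples)
    arr <- matrix(fill, prod(sizes), nf)
    arr[pos, ] <- ds$samples
    dim(arr) <- c(sizes, nf)
  }
  list(array = arr, labels = dl$labels, values = dl$values)
}

#' Move dimensions between the feature and sample axes
#'
#' Moves one or more named dimensions from one axis to the other, reshaping
#' the samples matrix so that each (old row/column, moved position)
#' combination becomes a distinct element on the target axis. The dataset
#' must be dense in the moved dimensions: every combination of a moved
#' position with a remaining position occurs exactly once. A typical use is
#' making \code{time} a sample dimension before time-generalization
#' analysis.
#'
#' New elements on the target axis are ordered with the original elements
#' varying fastest and the moved positions slowest.
#'
#' @param ds an \code{mvpa_dataset}.
#' @param labels dimension names to move; they must currently live on the
#'   axis opposite to \code{target_axis}.
#' @param target_axis \code{"samples"} or \code{"features"}.
#' @return the transposed \code{mvpa_dataset}.
#' @export
dim_transpose <- function(ds, labels,
                          target_axis = c("samples", "features")) {
  target_axis <- match.arg(target_axis)
  from_dim <- if (target_axis == "samples") "fdim" else "sdim"
  dl <- ds$a[[from_dim]]
  if (is.null(dl) || !all(labels %in% dl$labels)) {
    missing_lab <- setdiff(labels, if (is.null(dl)) character(0) else dl$labels)
    stop(sprintf("label(s) not on the source axis: %s",
                 paste(if (length(missing_lab)) missing_lab else labels,
                       collapse = ", ")), call. = FALSE)
  }
  from_attrs <- if (target_axis == "samples") ds$fa else ds$sa
  moved <- dl$labels[dl$labels %in% labels]
  kept <- setdiff(dl$labels, moved)
  moved_dl <- dim_list(moved, dl$values[match(moved, dl$labels)])
  m_pos <- grid_positions(from_attrs, moved_dl)
  m_levels <- sort(unique(m_pos))
  n_m <- length(m_levels)
  m_rank <- match(m_pos, m_levels)

  # canonical ordering: within each moved-position group, original order
  groups <- split(seq_along(m_pos), m_rank)
  n_r <- length(groups[[1]])
  if (!all(vapply(groups, length, integer(1)) == n_r)) {
    stop("dataset is not dense in the moved dimension(s)", call. = FALSE)
  }
  other_cols <- setdiff(names(from_attrs), moved)
  ref <- from_attrs[groups[[1]], other_cols, drop = FALSE]
  for (g in groups[-1]) {
    cur <- from_attrs[g, other_cols, drop = FALSE]
    if (!isTRUE(all.equal(as.list(ref), as.list(cur),
                          check.attributes = FALSE))) {
      stop("dataset is not dense in the moved dimension(s): remaining ",
           "positions differ across moved positions", call. = FALSE)
    }
  }
  rownames(ref) <- NULL

  # index combos of the moved labels for each moved-position level
  sizes <- vapply(moved_dl$values, length, integer(1))
  level_idx <- arrayInd(m_levels, .dim = sizes)

  if (target_axis == "samples") {
    n_old <- nrow(ds$samples)
    new_samples <- matrix(NA_real_, n_old * n_m, n_r)
    for (m in seq_len(n_m)) {
      rows <- (m - 1L) * n_old + seq_len(n_old)
      new_samples[rows, ] <- ds$samples[, groups[[m]], drop = FALSE]
    }
    new_sa <- ds$sa[rep(seq_len(n_old), n_m), , drop = FALSE]
    rownames(new_sa) <- NULL
    for (j in seq_along(moved)) {
      new_sa[[moved[j]]] <- as.integer(level_idx[rep(seq_len(n_m),
                                                     each = n_old), j])
    }
    sdim <- ds$a$sdim
    if (is.null(sdim)) sdim <- dim_list(character(0), list())
    ds$a$sdim <- dim_list(c(sdim$labels, moved),
                          c(sdim$values, moved_dl$values))
    ds$a$fdim <- if (length(kept) > 0) {
      dim_list(kept, dl$values[match(kept, dl$labels)])
    } else NULL
    ds$samples <- new_samples
    ds$sa <- new_sa
    ds$fa <- ref
  } else {
    blocks <- vector("list", n_m)
    for (m in seq_len(n_m)) {
      blocks[[m]] <- ds$samples[groups[[m]], , drop = FALSE]
    }
    # block m holds all original features at moved position m
    new_samples <- do.call(cbind, blocks)
    nf0 <- ncol(ds$samples)
    new_fa <- ds$fa[rep(seq_len(nf0), n_m), , drop = FALSE]
    rownames(new_fa) <- NULL
    for (j in seq_along(moved)) {
      new_fa[[moved[j]]] <- as.integer(level_idx[rep(seq_len(n_m),
                                                     each = nf0), j])
    }
    fdim <- ds$a$fdim
    if (is.null(fdim)) fdim <- dim_list(character(0), list())
    ds$a$fdim <- dim_list(c(fdim$labels, moved),
                          c(fdim$values, moved_dl$values))
    ds$a$sdim <- if (length(kept) > 0) {
      dim_list(kept, dl$values[match(kept, dl$labels)])
    } else NULL
    ds$samples <- new_samples
    ds$fa <- new_fa
    ds$sa <- ref
  }
  ds
}

#' Rename a dataset dimension
#'
#' Renames a dimension label on either axis together with its index column;
#' coordinate values are untouched.
#'
#' @param ds an \code{mvpa_dataset}.
#' @param old_label existing dimension name.
#' @param new_label replacement name; must not collide with any existing
#'   dimension label or attribute column.
#' @return the renamed \code{mvpa_dataset}.
#' @export
dim_rename <- function(ds, old_label, new_label) {
  in_fdim <- !is.null(ds$a$fdim) && old_label %in% ds$a$fdim$labels
  in_sdim <- !is.null(ds$a$sdim) && old_label %in% ds$a$sdim$labels
  if (!in_fdim && !in_sdim) {
    stop(sprintf("no dimension named '%s'", old_label), call. = FALSE)
  }
  all_labels <- c(ds$a$fdim$labels, ds$a$sdim$labels,
                  names(ds$fa), names(ds$sa))
  if (new_label %in% setdiff(all_labels, old_label)) {
    stop(sprintf("label '%s' already in use", new_label), call. = FALSE)
  }
  if (in_fdim) {
    i <- match(old_label, ds$a$fdim$labels)
    ds$a$fdim$labels[i] <- new_label
    names(ds$a$fdim$values)[i] <- new_label
    names(ds$fa)[names(ds$fa) == old_label] <- new_label
  } else {
    i <- match(old_label, ds$a$sdim$labels)
    ds$a$sdim$labels[i] <- new_label
    names(ds$a$sdim$values)[i] <- new_label
    names(ds$sa)[names(ds$sa) == old_label] <- new_label
  }
  ds
}
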