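new_neighborhood <- function(neighbors, fa, a, origin) {
  structure(list(neighbors = neighbors, fa = fa, a = a, origin = origin),
            class = "mvpa_neighborhood")
}

#' @export
print.mvpa_neighborhood <- function(x, ...) {
  sizes <- lengths(x$neighbors)
  cat(sprintf("mvpa_neighborhood: %d centers over %d input features\n",
              length(x$neighbors), x$origin$n_features))
  cat(sprintf("  neighbors per center: %d..%d (median %g)\n",
              min(sizes), max(sizes), stats::median(sizes)))
  if (!is.null(x$a$fdim))
    cat("  output fdim:", paste(x$a$fdim$labels, collapse = " x "), "\n")
  invisible(x)
}

neighborhood_origin <- function(ds) {
  list(n_features = ncol(ds$samples),
       fdim_labels = if (is.null(ds$a$fdim)) character(0)
                     else ds$a$fdim$labels)
}

#' Spherical voxel neighborhood
#'
#' For every voxel (center) selects the voxels within a fixed world-space
#' radius, or the fixed number of nearest voxels (expanding the radius per
#' center). Distances are Euclidean in world mm, computed through the
#' volume affine. The output feature space equals the input space (one
#' center per voxel); the center itself is always included. In count mode
#' ties are broken deterministically by (distance, feature index).
#'
#' @param ds volumetric \code{mvpa_dataset} (with \code{i,j,k} dimensions
#'   and \code{a$vol}).
#' @param radius sphere radius in mm (closed ball), or
#' @param count number of nearest voxels to select; exactly one of
#'   \code{radius}/\code{count} must be given.
#' @return an \code{mvpa_neighborhood}.
#' @export
spherical_neighborhood <- function(ds, radius = NULL, count = NULL) {
  if (is.null(ds$a$vol) || is.null(ds$a$fdim) ||
      !all(c("i", "j", "k") %in% ds$a$fdim$labels)) {
    stop("spherical_neighborhood requires volume geometry", call. = FALSE)
  }
  if (is.null(radius) == is.null(count)) {
    stop("give exactly one of radius or count", call. = FALSE)
  }
  nf <- ncol(ds$samples)
  if (!is.null(count) && count > nf) {
    stop(sprintf("count %d exceeds %d features", count, nf), call. = FALSE)
  }
  vox <- vapply(c("i", "j", "k"), function(lab) {
    as.numeric(ds$a$fdim$values[[match(lab, ds$a$fdim$labels)]][ds$fa[[lab]]])
  }, numeric(nf))
  vox <- matrix(vox, nrow = nf, ncol = 3)
  world <- cbind(vox, 1) %*% t(ds$a$vol$mat)   # nf x 4
  world <- world[, 1:3, drop = FALSE]
  neighbors <- vector("list", nf)
  for (f in seq_len(nf)) {
    d2 <- (world[, 1] - world[f, 1])^2 +
          (world[, 2] - world[f, 2])^2 +
          (world[, 3] - world[f, 3])^2
    if (!is.null(radius)) {
      neighbors[[f]] <- which(d2 <= radius^2)
    } else {
      ord <- order(d2, seq_len(nf))
      neighbors[[f]] <- sort(ord[seq_len(count)])
    }
  }
  new_neighborhood(neighbors, fa = ds$fa, a = ds$a,
                   origin = neighborhood_origin(ds))
}

#' Interval neighborhood over a time or frequency dimension
#'
#' One center per position of the named dimension; a center at position p
#' selects all features whose position along that dimension lies within
#' \code{p - radius .. p + radius} (truncated at the boundaries), across
#' all other dimensions. A radius of zero selects each bin itself (still
#' across all channels etc.). The output feature space has only the named
#' dimension.
#'
#' @param ds an \code{mvpa_dataset}.
#' @param label name of a feature dimension (e.g. \code{"time"}).
#' @param radius non-negative integer radius in bins.
#' @return an \code{mvpa_neighborhood}.
#' @export
interval_neighborhood <- function(ds, label, radius) {
  if (is.null(ds$a$fdim) || !label %in% ds$a$fdim$labels) {
    stop(sprintf("unknown feature dimension '%s'", label), call. = FALSE)
  }
  stopifnot(radius >= 0)
  vals <- ds$a$fdim$values[[match(label, ds$a$fdim$labels)]]
  idx <- ds$fa[[label]]
  npos <- length(vals)
  neighbors <- lapply(seq_len(npos), function(p) {
    which(abs(idx - p) <= radius)
  })
  fa <- data.frame(seq_len(npos))
  names(fa) <- label
  a <- ds$a
  a$fdim <- dim_list(label, list(vals))
  a$vol <- NULL
  new_neighborhood(neighbors, fa = fa, a = a,
                   origin = neighborhood_origin(ds))
}

# 2-D location table for the sensor groups present in the dataset
layout_locations <- function(layout, groups) {
  loc <- lapply(groups, function(g) {
    members <- layout[layout$group == g, , drop = FALSE]
    comb <- members[members$kind == "combined", , drop = FALSE]
    ref <- if (nrow(comb) > 0) comb[1, ] else members[1, ]
    data.frame(group = g, x = mean(members$x), y = mean(members$y),
               combined = if (nrow(comb) > 0) comb$channel[1]
                          else ref$channel,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, loc)
}

#' Channel neighborhood over an M/EEG sensor layout
#'
#' One center per output channel. A center's neighbor sensor locations are
#' the \code{count} nearest locations (or all within \code{radius}, in
#' layout units) by planar 2-D distance; its neighbor features are all
#' features, at every time/frequency position, whose channel belongs to a
#' neighbor location. With \code{chantype = "combined_from_planar"} the
#' input channels are planar gradiometers but the output (center) channels
#' are the per-location combined gradiometers, and both planar channels of
#' every selected location are included together.
#'
#' @param ds an \code{mvpa_dataset} with a \code{chan} feature dimension
#'   whose channel names appear in the layout.
#' @param layout an \code{mvpa_layout} from \code{\link{load_layout}}.
#' @param count number of nearest sensor locations, or
#' @param radius layout-unit radius; exactly one of the two must be given.
#' @param chantype \code{"same"} (output channels = input channels) or
#'   \code{"combined_from_planar"}.
#' @return an \code{mvpa_neighborhood} with output fdim \code{chan}.
#' @export
channel_neighborhood <- function(ds, layout, count = NULL, radius = NULL,
                                 chantype = c("same",
                                              "combined_from_planar")) {
  chantype <- match.arg(chantype)
  if (is.null(ds$a$fdim) || !"chan" %in% ds$a$fdim$labels) {
    stop("dataset has no 'chan' feature dimension", call. = FALSE)
  }
  if (is.null(radius) == is.null(count)) {
    stop("give exactly one of radius or count", call. = FALSE)
  }
  chan_vals <- as.character(ds$a$fdim$values[[match("chan",
                                                    ds$a$fdim$labels)]])
  unknown <- setdiff(chan_vals, layout$channel)
  if (length(unknown) > 0) {
    stop("channels missing from layout: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  groups_present <- unique(layout$group[match(chan_vals, layout$channel)])
  locs <- layout_locations(layout, groups_present)
  if (!is.null(count) && count > nrow(locs)) {
    stop(sprintf("count %d exceeds %d sensor locations",
                 count, nrow(locs)), call. = FALSE)
  }

  if (chantype == "combined_from_planar") {
    center_names <- locs$combined
    center_xy <- cbind(locs$x, locs$y)
  } else {
    center_names <- chan_vals
    center_xy <- cbind(layout$x[match(chan_vals, layout$channel)],
                       layout$y[match(chan_vals, layout$channel)])
  }
  n_centers <- length(center_names)
  feat_chan <- chan_vals[ds$fa$chan]
  feat_group <- layout$group[match(feat_chan, layout$channel)]

  neighbors <- vector("list", n_centers)
  for (ci in seq_len(n_centers)) {
    d2 <- (locs$x - center_xy[ci, 1])^2 + (locs$y - center_xy[ci, 2])^2
    if (!is.null(radius)) {
      sel <- which(d2 <= radius^2)
    } else {
      ord <- order(d2, seq_len(nrow(locs)))
      sel <- ord[seq_len(count)]
    }
    sel_groups <- locs$group[sel]
    neighbors[[ci]] <- which(feat_group %in% sel_groups)
  }
  fa <- data.frame(chan = seq_len(n_centers))
  a <- ds$a
  a$fdim <- dim_list("chan", list(center_names))
  a$vol <- NULL
  new_neighborhood(neighbors, fa = fa, a = a,
                   origin = neighborhood_origin(ds))
}

#' Cross neighborhoods into a higher-dimensional neighborhood
#'
#' Builds the Cartesian product of the parts' centers (the first part's
#' centers vary fastest); each crossed center's neighbors are the
#' intersection of the parts' neighbor sets. The output feature dimensions
#' are the concatenation of the parts' dimensions, which must be disjoint.
#' Centers whose intersection is empty are retained with an empty neighbor
#' list (the searchlight writes NaN there).
#'
#' @param ds the \code{mvpa_dataset} all parts were built from.
#' @param parts list of \code{mvpa_neighborhood} objects over the same
#'   input space.
#' @return an \code{mvpa_neighborhood}.
#' @export
cross_neighborhood <- function(ds, parts) {
  stopifnot(length(parts) >= 1)
  nf <- ncol(ds$samples)
  all_labels <- character(0)
  for (p in parts) {
    if (p$origin$n_features != nf) {
      stop("neighborhood was built from a different input space",
           call. = FALSE)
    }
    labs <- p$a$fdim$labels
    if (any(labs %in% all_labels)) {
      stop("crossed neighborhoods have colliding dimension labels: ",
           paste(intersect(labs, all_labels), collapse = ", "),
           call. = FALSE)
    }
    all_labels <- c(all_labels, labs)
  }
  counts <- vapply(parts, function(p) length(p$neighbors), integer(1))
  combos <- index_grid(counts)   # first part varies fastest
  n_centers <- nrow(combos)
  neighbors <- vector("list", n_centers)
  for (ci in seq_len(n_centers)) {
    nb <- parts[[1]]$neighbors[[combos[ci, 1]]]
    for (pi in seq_along(parts)[-1]) {
      nb <- intersect(nb, parts[[pi]]$neighbors[[combos[ci, pi]]])
    }
    neighbors[[ci]] <- sort(nb)
  }
  fa_parts <- lapply(seq_along(parts), function(pi) {
    part_fa <- parts[[pi]]$fa[combos[, pi], , drop = FALSE]
    rownames(part_fa) <- NULL
    part_fa
  })
  fa <- do.call(cbind, fa_parts)
  fa <- fa[, !duplicated(names(fa)), drop = FALSE]
  labels <- unlist(lapply(parts, function(p) p$a$fdim$labels))
  values <- unlist(lapply(parts, function(p) p$a$fdim$values),
                   recursive = FALSE)
  a <- parts[[1]]$a
  a$fdim <- dim_list(labels, values)
  new_neighborhood(neighbors, fa = fa, a = a,
                   origin = neighborhood_origin(ds))
}
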