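#' Construct an MVPA dataset
#'
#' The dataset is the single data currency of the package: a numeric
#' samples-by-features matrix together with per-sample attributes (\code{sa}),
#' per-feature attributes (\code{fa}) and general attributes (\code{a}).
#' Rows of \code{samples} are observations (volumes, trial epochs,
#' per-condition statistic maps); columns are measurement locations (voxels,
#' channel-by-time bins, ...).
#'
#' Two \code{sa} columns have reserved meaning: \code{targets} holds integer
#' condition labels and \code{chunks} holds integer labels marking groups of
#' samples that are statistically independent (for example acquisition runs).
#'
#' Multi-dimensional feature spaces are described by \code{a$fdim}, a
#' dimension list with fields \code{labels} (ordered dimension names) and
#' \code{values} (for each label, the ordered coordinate values). For every
#' label there is an \code{fa} column of the same name holding 1-based
#' positions into the label's value list. The sample axis can carry an
#' analogous \code{a$sdim}. Indices are 1-based throughout.
#'
#' Volumetric datasets additionally carry \code{a$vol}, a list with
#' \code{mat} (4x4 affine mapping 1-based voxel indices to world mm) and
#' \code{dim} (the 3-element grid size).
#'
#' @param samples numeric matrix, n_samples x n_features; NaN allowed.
#' @param sa data.frame of per-sample attributes (or NULL).
#' @param fa data.frame of per-feature attributes (or NULL).
#' @param a list of general attributes (or NULL); recognised elements are
#'   \code{fdim}, \code{sdim} and \code{vol}.
#' @param targets,chunks optional convenience vectors copied into \code{sa}.
#' @return an object of class \code{mvpa_dataset}.
#' @examples
#' ds <- mvpa_dataset(matrix(rnorm(12), 4, 3),
#'                    targets = c(1, 2, 1, 2), chunks = c(1, 1, 2, 2))
#' validate_dataset(ds)
#' @export
mvpa_dataset <- function(samples, sa = NULL, fa = NULL, a = NULL,
                         targets = NULL, chunks = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(sa)) {
    sa <- data.frame(row.names = seq_len(nrow(samples)))
  }
  if (is.null(fa)) {
    fa <- data.frame(row.names = seq_len(ncol(samples)))
  }
  if (is.null(a)) a <- list()
  if (!is.null(targets)) sa$targets <- as.integer(targets)
  if (!is.null(chunks)) sa$chunks <- as.integer(chunks)
  ds <- structure(list(samples = samples, sa = sa, fa = fa, a = a),
                  class = "mvpa_dataset")
  ds
}

#' Create a dimension list
#'
#' @param labels character vector of dimension names (order defines the
#'   unflatten axis order).
#' @param values list of coordinate-value vectors, one per label.
#' @return a list with elements \code{labels} and \code{values}.
#' @export
dim_list <- function(labels, values) {
  stopifnot(length(labels) == length(values))
  names(values) <- labels
  list(labels = as.character(labels), values = values)
}

#' @export
print.mvpa_dataset <- function(x, ...) {
  cat(sprintf("mvpa_dataset: %d samples x %d features\n",
              nrow(x$samples), ncol(x$samples)))
  if (ncol(x$sa) > 0)
    cat("  sa:", paste(names(x$sa), collapse = ", "), "\n")
  if (ncol(x$fa) > 0)
    cat("  fa:", paste(names(x$fa), collapse = ", "), "\n")
  if (!is.null(x$a$fdim))
    cat("  fdim:", paste(x$a$fdim$labels, collapse = " x "), "\n")
  if (!is.null(x$a$sdim))
    cat("  sdim:", paste(x$a$sdim$labels, collapse = " x "), "\n")
  invisible(x)
}

check_dim_list <- function(dl, where) {
  out <- character(0)
  if (!is.list(dl) || is.null(dl$labels) || is.null(dl$values)) {
    return(sprintf("%s: must have fields labels and values", where))
  }
  if (length(dl$labels) != length(dl$values)) {
    out <- c(out, sprintf("%s: labels and values lengths differ", where))
  }
  if (anyDuplicated(dl$labels)) {
    out <- c(out, sprintf("%s: duplicate labels", where))
  }
  for (i in seq_along(dl$values)) {
    v <- dl$values[[i]]
    if (length(v) == 0) {
      out <- c(out, sprintf("%s: values for label '%s' empty",
                            where, dl$labels[i]))
    } else if (anyDuplicated(v)) {
      out <- c(out, sprintf("%s: values for label '%s' not unique",
                            where, dl$labels[i]))
    }
  }
  out
}

#' Validate an MVPA dataset
#'
#' Checks every structural invariant of the dataset and reports all
#' violations; it never raises an error itself. An empty character vector
#' means the dataset is well-formed.
#'
#' @param ds an \code{mvpa_dataset}.
#' @return character vector of human-readable violation descriptions
#'   (empty if none).
#' @export
validate_dataset <- function(ds) {
  out <- character(0)
  if (!inherits(ds, "mvpa_dataset")) {
    return("not an mvpa_dataset object")
  }
  if (!is.matrix(ds$samples) || !is.numeric(ds$samples)) {
    return("samples: must be a numeric matrix")
  }
  ns <- nrow(ds$samples)
  nf <- ncol(ds$samples)
  for (nm in names(ds$sa)) {
    if (length(ds$sa[[nm]]) != ns) {
      out <- c(out, sprintf("sa.%s: length %d, expected %d samples",
                            nm, length(ds$sa[[nm]]), ns))
    }
  }
  if (nrow(ds$sa) != ns) {
    out <- c(out, sprintf("sa: %d rows, expected %d", nrow(ds$sa), ns))
  }
  for (nm in names(ds$fa)) {
    if (length(ds$fa[[nm]]) != nf) {
      out <- c(out, sprintf("fa.%s: length %d, expected %d features",
                            nm, length(ds$fa[[nm]]), nf))
    }
  }
  if (nrow(ds$fa) != nf) {
    out <- c(out, sprintf("fa: %d rows, expected %d", nrow(ds$fa), nf))
  }
  out <- c(out, check_dim_axis(ds, "fdim"), check_dim_axis(ds, "sdim"))
  if (!is.null(ds$a$vol)) {
    vol <- ds$a$vol
    if (!is.matrix(vol$mat) || !all(dim(vol$mat) == c(4, 4)) ||
        abs(det(vol$mat)) < 1e-12) {
      out <- c(out, "a.vol.mat: must be an invertible 4x4 matrix")
    }
    if (length(vol$dim) != 3 || any(vol$dim < 1)) {
      out <- c(out, "a.vol.dim: must be 3 positive integers")
    } else if (!is.null(ds$a$fdim)) {
      for (ax in seq_along(c("i", "j", "k"))) {
        lab <- c("i", "j", "k")[ax]
        idx <- match(lab, ds$a$fdim$labels)
        if (!is.na(idx) &&
            length(ds$a$fdim$values[[idx]]) != vol$dim[ax]) {
          out <- c(out, sprintf(
            "a.vol.dim[%d]: %d does not match fdim '%s' length %d",
            ax, vol$dim[ax], lab, length(ds$a$fdim$values[[idx]])))
        }
      }
    }
  }
  out
}

check_dim_axis <- function(ds, which_dim) {
  dl <- ds$a[[which_dim]]
  if (is.null(dl)) return(character(0))
  out <- check_dim_list(dl, paste0("a.", which_dim))
  if (length(out) > 0) return(out)
  attrs <- if (which_dim == "fdim") ds$fa else ds$sa
  attr_name <- if (which_dim == "fdim") "fa" else "sa"
  n <- if (which_dim == "fdim") ncol(ds$samples) else nrow(ds$samples)
  for (i in seq_along(dl$labels)) {
    lab <- dl$labels[i]
    col <- attrs[[lab]]
    if (is.null(col)) {
      out <- c(out, sprintf("%s.%s: missing column for a.%s label",
                            attr_name, lab, which_dim))
      next
    }
    nv <- length(dl$values[[i]])
    if (length(col) == n) {
      bad <- !is.finite(col) | col < 1 | col > nv | col != round(col)
      if (any(bad)) {
        out <- c(out, sprintf(
          "%s.%s: indices must be integers in [1, %d] (%d invalid)",
          attr_name, lab, nv, sum(bad)))
      }
    }
  }
  out
}

#' Assert that a dataset is well-formed
#'
#' Raises an error listing all invariant violations; convenience wrapper
#' around \code{\link{validate_dataset}}.
#' @param ds an \code{mvpa_dataset}.
#' @return the dataset, invisibly.
#' @export
assert_dataset <- function(ds) {
  v <- validate_dataset(ds)
  if (length(v) > 0) {
    stop("invalid dataset:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  }
  invisible(ds)
}

resolve_selector <- function(selector, n, axis) {
  if (is.logical(selector)) {
    if (length(selector) != n) {
      stop(sprintf("logical mask of length %d does not match %d %s",
                   length(selector), n, axis), call. = FALSE)
    }
    which(selector)
  } else {
    selector <- as.integer(selector)
    if (length(selector) > 0 && all(selector < 0)) {
      selector <- seq_len(n)[selector]   # R-style negative exclusion
    }
    if (length(selector) > 0 && (min(selector) < 1 || max(selector) > n)) {
      stop(sprintf("index out of range for %d %s", n, axis), call. = FALSE)
    }
    selector
  }
}

#' Select samples or features of a dataset
#'
#' Subsets (or reorders) rows or columns of the samples matrix together with
#' the corresponding attribute table; the other axis and the general
#' attributes are untouched. Typical uses are region-of-interest selection
#' along features and train/test splitting along samples.
#'
#' @param ds an \code{mvpa_dataset}.
#' @param selector integer index vector (kept in the given order) or logical
#'   mask of the axis length.
#' @param axis \code{"samples"} (rows) or \code{"features"} (columns).
#' @return the sliced \code{mvpa_dataset}.
#' @examples
#' ds <- mvpa_dataset(matrix(1:12, 3, 4), targets = 1:3, chunks = 1:3)
#' slice_dataset(ds, c(3, 1), "samples")$sa$targets   # 3 1
#' @export
slice_dataset <- function(ds, selector,
                          axis = c("samples", "features")) {
  axis <- match.arg(axis)
  if (axis == "samples") {
    idx <- resolve_selector(selector, nrow(ds$samples), "samples")
    ds$samples <- ds$samples[idx, , drop = FALSE]
    ds$sa <- ds$sa[idx, , drop = FALSE]
    rownames(ds$sa) <- NULL
  } else {
    idx <- resolve_selector(selector, ncol(ds$samples), "features")
    ds$samples <- ds$samples[, idx, drop = FALSE]
    ds$fa <- ds$fa[idx, , drop = FALSE]
    rownames(ds$fa) <- NULL
  }
  ds
}

same_table <- function(x, y) {
  isTRUE(all.equal(as.list(x), as.list(y), check.attributes = FALSE)) &&
    identical(names(x), names(y))
}

#' Merge datasets along the sample or feature axis
#'
#' Stacking along samples requires identical feature attributes and general
#' attributes across parts (the parts describe the same feature space);
#' stacking along features requires identical sample attributes. The stacked
#' axis's attribute tables are concatenated.
#'
#' @param parts non-empty list of \code{mvpa_dataset} objects.
#' @param axis \code{"samples"} or \code{"features"}.
#' @return the merged \code{mvpa_dataset}.
#' @export
stack_datasets <- function(parts, axis = c("samples", "features")) {
  axis <- match.arg(axis)
  if (!is.list(parts) || length(parts) == 0) {
    stop("parts must be a non-empty list of datasets", call. = FALSE)
  }
  first <- parts[[1]]
  if (axis == "samples") {
    for (p in parts[-1]) {
      for (nm in union(names(first$fa), names(p$fa))) {
        if (!identical_column(first$fa[[nm]], p$fa[[nm]])) {
          stop(sprintf("fa.%s differs between stacked parts", nm),
               call. = FALSE)
        }
      }
      if (!isTRUE(all.equal(first$a, p$a))) {
        stop("dataset attributes 'a' differ between stacked parts",
             call. = FALSE)
      }
      if (!identical(sort(names(first$sa)), sort(names(p$sa)))) {
        stop("sa columns differ between stacked parts", call. = FALSE)
      }
    }
    first$samples <- do.call(rbind, lapply(parts, `[[`, "samples"))
    sas <- lapply(parts, function(p) p$sa[names(first$sa)])
    first$sa <- do.call(rbind, sas)
    rownames(first$sa) <- NULL
  } else {
    for (p in parts[-1]) {
      for (nm in union(names(first$sa), names(p$sa))) {
        if (!identical_column(first$sa[[nm]], p$sa[[nm]])) {
          stop(sprintf("sa.%s differs between stacked parts", nm),
               call. = FALSE)
        }
      }
      if (!identical(sort(names(first$fa)), sort(names(p$fa)))) {
        stop("fa columns differ between stacked parts", call. = FALSE)
      }
    }
    first$samples <- do.call(cbind, lapply(parts, `[[`, "samples"))
    fas <- lapply(parts, function(p) p$fa[names(first$fa)])
    first$fa <- do.call(rbind, fas)
    rownames(first$fa) <- NULL
  }
  first
}

identical_column <- function(x, y) {
  if (is.null(x) && is.null(y)) return(TRUE)
  if (is.null(x) || is.null(y)) return(FALSE)
  isTRUE(all.equal(x, y, check.attributes = FALSE))
}
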