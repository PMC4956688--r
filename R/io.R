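#' Read a volumetric fMRI dataset from a NIfTI file
#'
#' Each volume becomes one sample; features are the voxels where the mask
#' is nonzero (all voxels when no mask is given), enumerated in column-major
#' grid order. The feature dimensions are \code{i}, \code{j}, \code{k} with
#' values \code{1..dim}; \code{a$vol$mat} holds the affine mapping 1-based
#' voxel indices to world mm (the NIfTI affine, which maps 0-based indices,
#' is shifted by one voxel accordingly). The world orientation is taken
#' from the file verbatim; no reorientation is performed.
#'
#' @param path path to a 3D or 4D NIfTI file (.nii or .nii.gz).
#' @param mask optional path to a mask NIfTI on the same grid.
#' @param targets,chunks optional per-sample vectors copied into \code{sa}.
#' @return an \code{mvpa_dataset}.
#' @export
read_fmri_volume <- function(path, mask = NULL,
                             targets = NULL, chunks = NULL) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file '",
                                           path, "': ", conditionMessage(e),
                                           call. = FALSE))
  arr <- as.array(img)
  nd <- length(dim(arr))
  if (nd == 3) {
    dim(arr) <- c(dim(arr), 1L)
  } else if (nd != 4) {
    stop(sprintf("expected 3D or 4D NIfTI, got %dD", nd), call. = FALSE)
  }
  d <- dim(arr)[1:3]
  n <- dim(arr)[4]
  affine0 <- unclass(RNifti::xform(img))  # maps 0-based voxel indices
  mat <- affine0
  mat[, 4] <- affine0 %*% c(-1, -1, -1, 1)  # maps 1-based indices

  samples <- t(matrix(arr, prod(d), n))
  grid <- index_grid(d)
  names(grid) <- c("i", "j", "k")
  ds <- mvpa_dataset(samples, fa = grid,
                     a = list(fdim = dim_list(c("i", "j", "k"),
                                              lapply(d, seq_len)),
                              vol = list(mat = mat, dim = as.integer(d))),
                     targets = targets, chunks = chunks)
  if (!is.null(mask)) {
    mask_arr <- as.array(RNifti::readNifti(mask))
    if (length(dim(mask_arr)) != 3 || !all(dim(mask_arr) == d)) {
      stop("mask grid does not match data grid", call. = FALSE)
    }
    ds <- slice_dataset(ds, which(as.vector(mask_arr) != 0), "features")
  }
  ds
}

#' Write a volumetric dataset to a NIfTI file
#'
#' Unflattens the dataset over its \code{i,j,k} dimensions (grid positions
#' without a feature receive \code{fill}) and writes a 3D (one sample) or
#' 4D (several samples) NIfTI file whose sform affine is derived from
#' \code{a$vol$mat}. Reading the file back reproduces the samples
#' bit-exactly on the mapped voxels.
#'
#' @param ds an \code{mvpa_dataset} with \code{i,j,k} feature dimensions
#'   and \code{a$vol}.
#' @param path output path (.nii or .nii.gz).
#' @param fill value for voxels not present in the dataset (default 0).
#' @return \code{path}, invisibly.
#' @export
write_fmri_volume <- function(ds, path, fill = 0) {
  if (is.null(ds$a$vol) || is.null(ds$a$fdim) ||
      !all(c("i", "j", "k") %in% ds$a$fdim$labels)) {
    stop("dataset has no volume geometry (a$vol with i,j,k dimensions)",
         call. = FALSE)
  }
  uf <- unflatten_dataset(ds, "features", fill = fill)
  arr <- uf$array                      # n x d1 x d2 x d3
  n <- dim(arr)[1]
  arr <- aperm(arr, c(2, 3, 4, 1))
  if (n == 1) dim(arr) <- dim(arr)[1:3]
  mat <- ds$a$vol$mat
  affine0 <- mat
  affine0[, 4] <- mat %*% c(1, 1, 1, 1)  # back to 0-based convention
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::sform(img) <- structure(affine0, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- portable container (.plds) ------------------------------------------

# numbers are serialized as %.17g strings so doubles round-trip exactly
encode_numbers <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x) & !is.nan(x)] <- "NA"
  out[is.nan(x)] <- "NaN"
  out
}

decode_numbers <- function(x) {
  x <- unlist(x, use.names = FALSE)
  out <- suppressWarnings(as.numeric(x))
  out[x == "NA"] <- NA_real_
  out
}

encode_value <- function(x) {
  if (is.null(x)) {
    list(type = "null")
  } else if (is.data.frame(x)) {
    list(type = "data.frame", nrow = nrow(x),
         columns = lapply(as.list(x), encode_value))
  } else if (is.matrix(x)) {
    list(type = "matrix", dim = dim(x), storage = storage.mode(x),
         data = if (is.numeric(x)) encode_numbers(as.vector(x))
                else as.vector(x))
  } else if (is.atomic(x)) {
    list(type = "vector", storage = storage.mode(x),
         data = if (is.double(x)) encode_numbers(x) else x)
  } else if (is.list(x)) {
    list(type = "list", names = names(x), items = lapply(x, encode_value))
  } else {
    stop("cannot serialize object of class ", class(x)[1], call. = FALSE)
  }
}

decode_value <- function(e) {
  switch(e$type,
    null = NULL,
    data.frame = {
      cols <- lapply(e$columns, decode_value)
      if (length(cols) == 0) {
        data.frame(row.names = seq_len(e$nrow))
      } else {
        as.data.frame(cols, stringsAsFactors = FALSE)
      }
    },
    matrix = {
      data <- if (e$storage %in% c("double", "integer", "numeric")) {
        v <- decode_numbers(e$data)
        if (e$storage == "integer") as.integer(v) else v
      } else unlist(e$data, use.names = FALSE)
      matrix(data, nrow = e$dim[[1]], ncol = e$dim[[2]])
    },
    vector = {
      v <- unlist(e$data, use.names = FALSE)
      if (is.null(v)) v <- vector(e$storage, 0)
      switch(e$storage,
             double = decode_numbers(e$data),
             integer = as.integer(v),
             logical = as.logical(v),
             character = as.character(v),
             v)
    },
    list = {
      items <- lapply(e$items, decode_value)
      if (!is.null(e$names)) names(items) <- unlist(e$names)
      items
    },
    stop("unknown container node type: ", e$type, call. = FALSE)
  )
}

PLDS_VERSION <- 1L

#' Save a dataset to a portable container file
#'
#' Writes the dataset to a self-describing hierarchical key-value text file
#' (JSON, extension \code{.plds}). Numeric data is stored at full precision
#' so the round trip through \code{\link{load_container}} is lossless,
#' including NaN positions. This is the package's interchange format for
#' M/EEG and other non-volumetric datasets.
#'
#' @param ds an \code{mvpa_dataset}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
save_container <- function(ds, path) {
  obj <- list(format = "plds", version = PLDS_VERSION,
              samples = encode_value(ds$samples),
              sa = encode_value(ds$sa),
              fa = encode_value(ds$fa),
              a = encode_value(ds$a))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Load a dataset from a portable container file
#'
#' @param path path to a file written by \code{\link{save_container}}.
#' @return the stored \code{mvpa_dataset}.
#' @export
load_container <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$format) || obj$format != "plds") {
    stop("not a plds container file: ", path, call. = FALSE)
  }
  if (is.null(obj$version) || obj$version != PLDS_VERSION) {
    stop(sprintf("unsupported container version %s (expected %d)",
                 as.character(obj$version), PLDS_VERSION), call. = FALSE)
  }
  if (is.null(obj$samples)) {
    stop("corrupt container: missing samples", call. = FALSE)
  }
  mvpa_dataset(decode_value(obj$samples),
               sa = decode_value(obj$sa),
               fa = decode_value(obj$fa),
               a = decode_value(obj$a))
}

# ---- channel layouts ------------------------------------------------------

#' Load a built-in channel layout
#'
#' A layout describes M/EEG sensor positions on a 2-D plane: one row per
#' channel with columns \code{channel}, \code{x}, \code{y}, \code{kind}
#' (\code{planar}, \code{combined} or \code{eeg}) and \code{group} (a
#' location identifier linking the two planar gradiometers at a sensor
#' location to their combined channel). Available layouts:
#' \describe{
#'   \item{toy9}{9 sensor locations on a 3x3 unit grid, with 9 pairs of
#'     planar gradiometers (\code{x1..x9}, \code{y1..y9}) and 9 combined
#'     channels (\code{c1..c9}).}
#'   \item{grid_eeg_16}{16 EEG electrodes on a 4x4 unit grid.}
#' }
#'
#' @param name layout name.
#' @return a data.frame of class \code{mvpa_layout}.
#' @export
load_layout <- function(name) {
  dir <- system.file("extdata", "layouts", package = "mvpamap")
  available <- sub("\\.tsv$", "", list.files(dir, pattern = "\\.tsv$"))
  if (!name %in% available) {
    stop(sprintf("unknown layout '%s'; available: %s",
                 name, paste(available, collapse = ", ")), call. = FALSE)
  }
  lay <- utils::read.delim(file.path(dir, paste0(name, ".tsv")),
                           stringsAsFactors = FALSE)
  lay$channel <- as.character(lay$channel)
  if (anyDuplicated(lay$channel)) {
    stop("layout has duplicate channel ids", call. = FALSE)
  }
  attr(lay, "layout_name") <- name
  class(lay) <- c("mvpa_layout", "data.frame")
  lay
}

# ---- text export ----------------------------------------------------------

#' Export a dataset as a tab-separated table
#'
#' One row per feature with its dimension coordinates, followed by one
#' column per sample. Only datasets with at most two feature dimensions can
#' be exported this way.
#'
#' @param ds an \code{mvpa_dataset} with <= 2 fdim labels.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
export_table <- function(ds, path) {
  labels <- if (is.null(ds$a$fdim)) character(0) else ds$a$fdim$labels
  if (length(labels) > 2) {
    stop(sprintf("cannot export %d feature dimensions as a table (max 2)",
                 length(labels)), call. = FALSE)
  }
  tab <- data.frame(row.names = seq_len(ncol(ds$samples)))
  for (lab in labels) {
    vals <- ds$a$fdim$values[[match(lab, labels)]]
    tab[[lab]] <- vals[ds$fa[[lab]]]
  }
  vals_mat <- t(ds$samples)
  colnames(vals_mat) <- paste0("sample_", seq_len(nrow(ds$samples)))
  tab <- cbind(tab, as.data.frame(format(vals_mat, digits = 15,
                                         trim = TRUE, scientific = NA),
                                  stringsAsFactors = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
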