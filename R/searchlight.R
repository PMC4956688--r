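#' Searchlight: apply a measure at every neighborhood center
#'
#' For each center of the neighborhood, slices the input dataset to the
#' center's neighbor features, applies the measure, and assembles the
#' single-column results as the columns of an information map. The output's
#' feature attributes and dimensions come from the neighborhood, the sample
#' attributes from the first center's measure result; all centers must
#' yield the same number of rows. Centers with no neighbors yield an NaN
#' column (with a warning). Results are assembled in center order
#' regardless of scheduling, so worker count never changes the output.
#'
#' @param ds an \code{mvpa_dataset}, structurally identical to the one the
#'   neighborhood was built from.
#' @param nbrhood an \code{mvpa_neighborhood}.
#' @param measure a function \code{measure(ds, opt)} returning a
#'   single-column dataset.
#' @param opt options passed to the measure; additionally
#'   \code{center_ids} (integer subset of centers to evaluate) and
#'   \code{n_workers} (forked parallel workers; default 1) are interpreted
#'   by the searchlight itself.
#' @return an \code{mvpa_dataset} with one feature per (selected) center.
#' @examples
#' \donttest{
#' ds <- make_toy_meeg(seed = 1)
#' nb <- interval_neighborhood(ds, "time", radius = 1)
#' map <- searchlight(ds, nb, crossvalidation_measure,
#'                    opt = list(classifier = classify_lda))
#' map$samples  # classification accuracy per time bin
#' }
#' @export
searchlight <- function(ds, nbrhood, measure, opt = list()) {
  if (ncol(ds$samples) != nbrhood$origin$n_features) {
    stop(sprintf(
      "dataset has %d features but neighborhood was built over %d",
      ncol(ds$samples), nbrhood$origin$n_features), call. = FALSE)
  }
  center_ids <- opt$center_ids
  if (is.null(center_ids)) center_ids <- seq_along(nbrhood$neighbors)
  n_workers <- if (is.null(opt$n_workers)) 1L else as.integer(opt$n_workers)
  opt$center_ids <- NULL
  opt$n_workers <- NULL

  eval_center <- function(ci) {
    nb <- nbrhood$neighbors[[ci]]
    if (length(nb) == 0) return(NULL)
    sub <- slice_dataset(ds, nb, "features")
    tryCatch(measure(sub, opt),
             error = function(e) stop(sprintf("center %d: %s", ci,
                                              conditionMessage(e)),
                                      call. = FALSE))
  }
  results <- if (n_workers > 1) {
    parallel::mclapply(center_ids, eval_center, mc.cores = n_workers)
  } else {
    lapply(center_ids, eval_center)
  }
  for (r in results) {
    if (inherits(r, "try-error") || inherits(r, "error")) stop(r)
  }
  nonempty <- !vapply(results, is.null, logical(1))
  if (!any(nonempty)) {
    stop("all selected centers have empty neighbor sets", call. = FALSE)
  }
  if (!all(nonempty)) {
    warning(sprintf("%d center(s) with no neighbors yield NaN",
                    sum(!nonempty)), call. = FALSE)
  }
  first <- results[nonempty][[1]]
  n_rows <- nrow(first$samples)
  out <- matrix(NaN, n_rows, length(center_ids))
  for (i in seq_along(results)) {
    r <- results[[i]]
    if (is.null(r)) next
    if (nrow(r$samples) != n_rows) {
      stop(sprintf(
        "center %d returned %d rows but center %d returned %d",
        center_ids[i], nrow(r$samples),
        center_ids[which(nonempty)[1]], n_rows), call. = FALSE)
    }
    out[, i] <- r$samples[, 1]
  }
  a <- nbrhood$a
  a$sdim <- first$a$sdim
  fa_out <- nbrhood$fa[center_ids, , drop = FALSE]
  rownames(fa_out) <- NULL
  mvpa_dataset(out, sa = first$sa, fa = fa_out, a = a)
}
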