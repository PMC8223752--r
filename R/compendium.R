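#' Expression compendium container
#'
#' A light container for a gene-by-sample log2 expression matrix plus a
#' per-sample annotation table.  A single study and a merged multi-study
#' compendium use the same structure; a merged compendium simply carries
#' more than one `dataset` label.  Annotation rows correspond 1:1 to the
#' columns of the matrix, in the same order.
#'
#' @param values numeric gene x sample matrix with unique rownames (gene
#'   ids) and colnames (sample ids).
#' @param annotations data.frame with at least a `sample_id` column matching
#'   the matrix columns; standard columns (`dataset`, `tissue`, `status`,
#'   `sex`, `treatment`, `das28`, `rf_status`, `pair_id`, `timepoint`) are
#'   added (empty) when absent. Empty string means missing; `das28` is
#'   numeric with `NA` for missing.
#' @param flags named list of provenance flags, e.g. `quantile_normalized`,
#'   `batch_adjusted`.
#' @return an object of class `compendium`.
#' @export
compendium <- function(values, annotations, flags = list()) {
  check_numeric_matrix(values, "values")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stopf("matrix rownames must be unique gene identifiers")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stopf("matrix colnames must be unique sample identifiers")
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(annotations))
    stopf("annotations must have a `sample_id` column")
  if (!setequal(annotations$sample_id, colnames(values)) ||
      nrow(annotations) != ncol(values))
    stopf("annotation rows must match matrix columns 1:1; missing: %s",
          paste(utils::head(setdiff(colnames(values), annotations$sample_id), 5),
                collapse = ", "))
  annotations <- annotations[match(colnames(values), annotations$sample_id), ,
                             drop = FALSE]
  rownames(annotations) <- NULL
  for (col in c("dataset", "tissue", "status", "sex", "treatment",
                "rf_status", "pair_id", "timepoint"))
    if (!col %in% names(annotations)) annotations[[col]] <- ""
  if (!"das28" %in% names(annotations)) annotations$das28 <- NA_real_
  annotations$das28 <- suppressWarnings(as.numeric(annotations$das28))
  structure(
    list(values = values, annotations = annotations,
         flags = utils::modifyList(
           list(quantile_normalized = FALSE, batch_adjusted = FALSE), flags)),
    class = "compendium")
}

#' @export
#' @method print compendium
print.compendium <- function(x, ...) {
  cat(sprintf("compendium: %d genes x %d samples, %d dataset(s)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$annotations$dataset))))
  st <- table(x$annotations$status)
  cat("  status:", paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  cat(sprintf("  quantile_normalized=%s batch_adjusted=%s\n",
              x$flags$quantile_normalized, x$flags$batch_adjusted))
  invisible(x)
}

#' @export
dim.compendium <- function(x) dim(x$values)

#' Subset a compendium by genes and/or samples
#'
#' @param x compendium.
#' @param genes optional character vector of gene ids to keep.
#' @param samples optional character vector of sample ids, or a logical/
#'   integer index over columns.
#' @return compendium restricted to the requested genes and samples.
#' @export
subset_compendium <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "compendium"))
  v <- x$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing))
      stopf("genes not present: %s", paste(utils::head(missing, 5), collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  ann <- x$annotations
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, colnames(v)) else
      seq_len(ncol(v))[samples]
    if (anyNA(idx)) stopf("unknown sample ids in subset")
    v <- v[, idx, drop = FALSE]
    ann <- ann[idx, , drop = FALSE]
  }
  compendium(v, ann, x$flags)
}
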