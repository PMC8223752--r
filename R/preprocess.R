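#' Elementwise log2 transform with offset
#'
#' @param x non-negative numeric matrix (or vector).
#' @param offset non-negative constant added before taking log2.
#' @return `log2(x + offset)`.
#' @export
log2_transform <- function(x, offset = 0) {
  if (offset < 0) stopf("offset must be non-negative")
  if (any(x < 0, na.rm = TRUE)) stopf("log2_transform requires values >= 0")
  log2(x + offset)
}

#' Intra-study quantile normalization
#'
#' Forces every sample column onto the identical distribution: the row-wise
#' mean of the per-column sorted values. Ties within a column receive the
#' mean of the reference values they span; within-column rank order is
#' preserved.
#'
#' @param x numeric gene x sample matrix with at least 2 columns.
#' @return matrix of the same shape; a single-column matrix is returned
#'   unchanged with a warning.
#' @export
quantile_normalize <- function(x) {
  check_numeric_matrix(x, "x")
  if (ncol(x) < 2) {
    warnf("quantile_normalize: single-column input returned unchanged")
    return(x)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Convert FPKM to log2(TPM + offset)
#'
#' Per sample, TPM rescales FPKM to a fixed library total of one million:
#' `TPM_ij = FPKM_ij / sum_i FPKM_ij * 1e6`, so each TPM column sums to
#' 1e6 and the transform is invariant to per-sample scaling of FPKM.
#'
#' @param fpkm non-negative matrix; every sample needs at least one nonzero
#'   value.
#' @param offset added before the log2 (default 0.1).
#' @return log2(TPM + offset) matrix.
#' @export
fpkm_to_log_tpm <- function(fpkm, offset = 0.1) {
  check_numeric_matrix(fpkm, "fpkm")
  if (any(fpkm < 0)) stopf("FPKM values must be >= 0")
  tot <- colSums(fpkm)
  if (any(tot == 0)) {
    bad <- colnames(fpkm)[tot == 0] %||% which(tot == 0)
    stopf("all-zero FPKM column(s): %s", paste(bad, collapse = ", "))
  }
  tpm <- sweep(fpkm, 2, tot, "/") * 1e6
  log2_transform(tpm, offset)
}

#' Merge studies on their common genes
#'
#' Restricts each study to the intersection of gene sets (sorted
#' lexicographically), concatenates the sample columns and keeps the
#' per-sample `dataset` label so the merged object can be batch-adjusted.
#'
#' @param studies list of >= 2 `compendium` objects (typically one dataset
#'   each).
#' @return a merged `compendium`.
#' @export
merge_studies <- function(studies) {
  if (length(studies) < 2) stopf("merge_studies needs at least 2 studies")
  stopifnot(all(vapply(studies, inherits, TRUE, "compendium")))
  common <- Reduce(intersect, lapply(studies, function(s) rownames(s$values)))
  if (length(common) == 0) stopf("no genes common to all studies")
  common <- sort(common)
  values <- do.call(cbind, lapply(studies, function(s)
    s$values[common, , drop = FALSE]))
  ann <- do.call(rbind, lapply(studies, function(s) s$annotations))
  if (anyDuplicated(colnames(values)))
    stopf("duplicate sample ids across studies")
  flags <- studies[[1]]$flags
  compendium(values, ann, flags)
}

#' Impute sex from mean Y-chromosome gene expression
#'
#' Computes the per-sample mean over the listed Y-genes and partitions the
#' samples by a deterministic 2-means clustering of these means (centers
#' initialized at the minimum and maximum).  The higher-mean group is
#' labelled male. Existing annotations are never overwritten: imputation
#' fills blanks only.
#'
#' @param x numeric gene x sample matrix (log2 scale).
#' @param y_gene_ids gene ids treated as Y-chromosome markers; at least one
#'   must be present in `x`.
#' @param annotated optional character vector of existing per-sample labels
#'   (`"male"`, `"female"`, or `""` for missing), in column order.
#' @param min_separation minimum distance between the two cluster centers
#'   (log2 units) for the imputation to be trusted; below it all blanks
#'   stay blank and a warning is raised.
#' @return character vector of per-sample sex labels.
#' @export
impute_sex <- function(x, y_gene_ids, annotated = NULL,
                       min_separation = 0.5) {
  check_numeric_matrix(x, "x")
  present <- intersect(y_gene_ids, rownames(x))
  if (length(present) == 0) stopf("none of the Y-genes are present in the matrix")
  ym <- colMeans(x[present, , drop = FALSE])
  out <- annotated %||% rep("", ncol(x))
  if (length(out) != ncol(x)) stopf("`annotated` must have one entry per sample")
  if (all(out != "")) return(out)
  centers <- matrix(c(min(ym), max(ym)), ncol = 1)
  if (diff(range(ym)) == 0) {
    warnf("impute_sex: Y-gene means are constant; leaving blanks")
    return(out)
  }
  km <- stats::kmeans(matrix(ym, ncol = 1), centers = centers)
  if (abs(diff(km$centers)) < min_separation) {
    warnf("impute_sex: cluster separation %.3f < %.2f; leaving blanks",
          abs(diff(km$centers)), min_separation)
    return(out)
  }
  male_cluster <- which.max(km$centers)
  imputed <- ifelse(km$cluster == male_cluster, "male", "female")
  out[out == ""] <- imputed[out == ""]
  out
}

#' Z-scale genes (optionally within groups)
#'
#' Per gene — within each group when `grouping` is given — subtracts the
#' mean and divides by the standard deviation.  Zero-variance genes map to
#' all-zeros with a warning rather than being dropped, so panel gene lists
#' keep their length.
#'
#' @param x numeric gene x sample matrix.
#' @param grouping optional per-sample labels (e.g. dataset of origin); the
#'   scaling is then applied separately inside each group.
#' @return matrix of the same shape.
#' @export
zscale_genes <- function(x, grouping = NULL) {
  check_numeric_matrix(x, "x")
  scale_block <- function(m) {
    mu <- rowMeans(m)
    sd <- apply(m, 1, stats::sd)
    zero <- sd == 0
    if (any(zero)) {
      warnf("zscale_genes: %d zero-variance gene(s) set to 0", sum(zero))
      sd[zero] <- 1
    }
    out <- (m - mu) / sd
    out[zero, ] <- 0
    out
  }
  if (is.null(grouping)) return(scale_block(x))
  if (length(grouping) != ncol(x)) stopf("grouping must have one label per sample")
  out <- x
  for (g in unique(grouping)) {
    idx <- grouping == g
    if (sum(idx) < 2) stopf("group '%s' has fewer than 2 samples", g)
    out[, idx] <- scale_block(x[, idx, drop = FALSE])
  }
  out
}
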