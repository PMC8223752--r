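# TSV dialects: matrix files have `gene_id` as the first column and one
# column per sample; annotation files carry the standard per-sample
# columns with "" for missing.  Doubles are written with 17 significant
# digits so a write/read round trip is bit-exact.

#' Write an expression matrix to TSV
#'
#' @param x gene x sample numeric matrix (or `compendium`, whose values
#'   are written).
#' @param path output file.
#' @export
write_matrix <- function(x, path) {
  if (inherits(x, "compendium")) x <- x$values
  check_numeric_matrix(x, "x")
  dt <- data.table::data.table(gene_id = rownames(x))
  for (j in seq_len(ncol(x))) dt[[colnames(x)[j]]] <- sprintf("%.17g", x[, j])
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' @param path matrix TSV (first column `gene_id`).
#' @param annotations optional annotation data.frame or path to an
#'   annotation TSV; when supplied the result is a [compendium()] and
#'   every matrix column must have an annotation row.
#' @return numeric matrix, or `compendium` when annotations are given.
#' @export
read_matrix <- function(path, annotations = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1))
  if (names(dt)[1] != "gene_id") stopf("first column must be `gene_id`")
  genes <- dt[[1]]
  if (anyDuplicated(genes))
    stopf("duplicate gene ids: %s",
          paste(utils::head(unique(genes[duplicated(genes)]), 5), collapse = ", "))
  m <- as.matrix(dt[, -1])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (is.null(annotations)) return(m)
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  missing <- setdiff(colnames(m), annotations$sample_id)
  if (length(missing))
    stopf("samples without annotations: %s",
          paste(utils::head(missing, 10), collapse = ", "))
  compendium(m, annotations[annotations$sample_id %in% colnames(m), ,
                            drop = FALSE])
}

#' Write a per-sample annotation table to TSV
#'
#' @param ann data.frame with `sample_id` plus the standard columns;
#'   missing values are written as empty strings.
#' @param path output file.
#' @export
write_annotations <- function(ann, path) {
  ann <- as.data.frame(ann)
  cols <- c("sample_id", "dataset", "tissue", "status", "sex", "treatment",
            "das28", "rf_status", "pair_id", "timepoint")
  for (col in setdiff(cols, names(ann)))
    ann[[col]] <- if (col == "das28") NA_real_ else ""
  ann <- ann[, cols]
  ann$das28 <- ifelse(is.na(ann$das28), "", sprintf("%.17g", ann$das28))
  data.table::fwrite(ann, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a per-sample annotation table from TSV
#'
#' @param path annotation TSV; empty strings are kept as "" (missing) and
#'   `das28` is parsed as numeric with `NA` for missing.
#' @return data.frame.
#' @export
read_annotations <- function(path) {
  ann <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL)
  ann <- as.data.frame(ann)
  if (!"sample_id" %in% names(ann)) stopf("annotation file lacks `sample_id`")
  if ("das28" %in% names(ann))
    ann$das28 <- suppressWarnings(as.numeric(ann$das28))
  ann
}

#' Write the ground-truth record of a synthetic compendium
#'
#' Serializes the gene-level and sample-level truth tables as a TSV pair
#' (`<prefix>_genes.tsv`, `<prefix>_samples.tsv`).
#'
#' @param truth the `truth` element of [generate_compendium()].
#' @param prefix output path prefix.
#' @export
write_ground_truth <- function(truth, prefix) {
  data.table::fwrite(truth$genes, paste0(prefix, "_genes.tsv"), sep = "\t")
  data.table::fwrite(truth$samples, paste0(prefix, "_samples.tsv"), sep = "\t")
  invisible(prefix)
}
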