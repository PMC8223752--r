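#' Principal-component scores of a gene-centered expression matrix
#'
#' SVD of the gene-centered matrix; sample scores for the first `k`
#' components with a deterministic sign convention (the largest-magnitude
#' gene loading of each component is made positive).
#'
#' @param x gene x sample matrix (or `compendium`).
#' @param k number of components (`k <= min(genes, samples)`).
#' @return list with `scores` (sample x k), `var_explained` (all
#'   components) and `loadings` (gene x k).
#' @export
pca_scores <- function(x, k) {
  if (inherits(x, "compendium")) x <- x$values
  check_numeric_matrix(x, "x")
  if (k > min(dim(x))) stopf("k = %d exceeds min(genes, samples) = %d",
                             k, min(dim(x)))
  xc <- x - rowMeans(x)
  sv <- svd(xc, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j)
    sign(sv$u[which.max(abs(sv$u[, j])), j]), 0)
  scores <- sweep(sv$v, 2, sv$d[seq_len(k)] * flip, "*")
  rownames(scores) <- colnames(x)
  colnames(scores) <- sprintf("PC%d", seq_len(k))
  loadings <- sweep(sv$u, 2, flip, "*")
  dimnames(loadings) <- list(rownames(x), colnames(scores))
  list(scores = scores, var_explained = sv$d^2 / sum(sv$d^2),
       loadings = loadings)
}

#' Batch predictability via random forest on principal components
#'
#' Splits the samples 2:1 (stratified by batch), trains a random forest
#' (500 trees) on the first `n_pc` principal-component scores to predict
#' the dataset of origin, and reports the multinomial log loss on the
#' held-out third with probabilities clipped to `[1e-15, 1 - 1e-15]`.
#' HIGHER loss means the batch is less predictable, i.e. better mixing
#' after adjustment; the uniform predictor over `C` balanced batches
#' scores exactly `log(C)`.
#'
#' @param x gene x sample matrix (or `compendium`).
#' @param batch per-sample batch labels (>= 2 batches, each present in
#'   train and test after the stratified split; a failed split is retried
#'   with the next seed up to 10 times).
#' @param n_pc number of components (default 20, capped at the matrix
#'   rank).
#' @param train_fraction training share of the split (default 2/3).
#' @param seed integer seed (drives the split and the forest).
#' @return multinomial log loss (a scalar), with attribute `n_pc`.
#' @export
batch_predictability <- function(x, batch, n_pc = 20, train_fraction = 2 / 3,
                                 seed = 1) {
  if (inherits(x, "compendium")) {
    batch <- batch %||% x$annotations$dataset
    x <- x$values
  }
  batch <- factor(as.character(batch))
  if (nlevels(batch) < 2) stopf("need >= 2 batches")
  n_pc <- min(n_pc, min(dim(x)) - 1)
  pcs <- pca_scores(x, n_pc)$scores

  split <- NULL
  for (try in 0:9) {
    sp <- stratified_split(as.character(batch), train_fraction, seed + try)
    if (setequal(unique(batch[sp$train]), levels(batch)) &&
        setequal(unique(batch[sp$test]), levels(batch))) { split <- sp; break }
  }
  if (is.null(split)) stopf("could not produce a split covering every batch")

  rf <- with_seed(seed, randomForest::randomForest(
    pcs[split$train, , drop = FALSE], batch[split$train], ntree = 500))
  prob <- stats::predict(rf, pcs[split$test, , drop = FALSE], type = "prob")
  prob <- pmin(pmax(prob, 1e-15), 1 - 1e-15)
  truth <- as.character(batch[split$test])
  ll <- -mean(log(prob[cbind(seq_along(truth), match(truth, colnames(prob)))]))
  attr(ll, "n_pc") <- n_pc
  ll
}

#' Kruskal-Wallis association of principal components with batch
#'
#' Tie-corrected Kruskal-Wallis test of each of the first `n_pc`
#' principal-component score vectors against the batch grouping, with the
#' chi-square (C - 1 df) p-value.  Low p on leading components indicates
#' batch-driven variance.
#'
#' @inheritParams batch_predictability
#' @param n_pc number of components tested (default 10).
#' @return data.frame `pc, H, p, var_explained`.
#' @export
pc_batch_kruskal <- function(x, batch = NULL, n_pc = 10) {
  if (inherits(x, "compendium")) {
    batch <- batch %||% x$annotations$dataset
    x <- x$values
  }
  batch <- factor(as.character(batch))
  if (nlevels(batch) < 2 || any(table(batch) < 2))
    stopf("need >= 2 batches with >= 2 samples each")
  n_pc <- min(n_pc, min(dim(x)) - 1)
  p <- pca_scores(x, n_pc)
  rows <- lapply(seq_len(n_pc), function(j) {
    v <- p$scores[, j]
    if (length(unique(v)) == 1) {
      warnf("PC%d has all-tied scores; p = 1", j)
      return(data.frame(pc = j, H = 0, p = 1,
                        var_explained = p$var_explained[j]))
    }
    kt <- stats::kruskal.test(v, batch)
    data.frame(pc = j, H = unname(kt$statistic), p = kt$p.value,
               var_explained = p$var_explained[j])
  })
  do.call(rbind, rows)
}

#' Label-free cluster separation of a gene subset
#'
#' PCA on the matrix restricted to `gene_subset`, then 2-means (25 seeded
#' restarts, best inertia) on the first two component scores.  Only after
#' clustering is the cluster with the higher case fraction mapped to
#' "case"; sensitivity, specificity, precision and recall follow from the
#' confusion matrix with case as the positive class.
#'
#' @param x gene x sample matrix (or `compendium`).
#' @param status_labels per-sample case/control labels.
#' @param gene_subset nonempty gene-id vector.
#' @param seed seed for the k-means restarts.
#' @return named vector `sensitivity, specificity, precision, recall`.
#' @export
kmeans_cluster_eval <- function(x, status_labels = NULL, gene_subset,
                                seed = 1) {
  if (inherits(x, "compendium")) {
    status_labels <- status_labels %||% x$annotations$status
    x <- x$values
  }
  if (length(gene_subset) == 0) stopf("gene_subset must be nonempty")
  y <- status01(status_labels)
  if (length(unique(y)) < 2) stopf("need both status classes")
  sub <- x[intersect(gene_subset, rownames(x)), , drop = FALSE]
  if (nrow(sub) == 0) stopf("no subset genes present in the matrix")
  k <- min(2, min(dim(sub)))
  pcs <- pca_scores(sub, k)$scores
  km <- with_seed(seed, stats::kmeans(pcs, centers = 2, nstart = 25))
  case_frac <- tapply(y, km$cluster, mean)
  case_cluster <- if (case_frac[1] == case_frac[2]) {
    # tie: call the larger cluster "control"
    which.min(table(km$cluster))
  } else as.integer(names(which.max(case_frac)))
  pred <- as.integer(km$cluster == case_cluster)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = tp / (tp + fn))
}
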