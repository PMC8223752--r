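#' Feature-selection configuration
#'
#' Parameters of the iterative cross-tissue selection loop: number of
#' resampling iterations, the stratified train/test split ratio, the
#' training-set FDR gate, the minimum absolute Pearson correlation with
#' case/control status, the maximum pairwise correlation tolerated before
#' redundancy pruning removes a gene, and the mean-test-AUC threshold a
#' gene must clear in both tissues to enter the final set.
#'
#' @param n_iterations resampling iterations (default 100).
#' @param split_ratio training fraction per class (default 0.8).
#' @param de_fdr BH-adjusted p gate inside the loop (default 0.05).
#' @param status_corr_min minimum `|r|` with status (default 0.25).
#' @param pairwise_corr_max redundancy threshold (default 0.8).
#' @param auc_threshold mean test-AUC gate (default 2/3).
#' @param base_seed iteration `i` uses seed `base_seed + i`.
#' @param covariate_cols annotation columns used as DE covariates inside
#'   the loop when present with > 1 level (default sex and treatment).
#' @return validated `fs_config` list.
#' @export
fs_config <- function(n_iterations = 100, split_ratio = 0.8, de_fdr = 0.05,
                      status_corr_min = 0.25, pairwise_corr_max = 0.8,
                      auc_threshold = 2 / 3, base_seed = 1,
                      covariate_cols = c("sex", "treatment")) {
  cfg <- as.list(environment())
  if (n_iterations < 1) stopf("n_iterations must be >= 1")
  if (split_ratio <= 0 || split_ratio >= 1) stopf("split_ratio must be in (0,1)")
  for (v in c(de_fdr, status_corr_min, pairwise_corr_max, auc_threshold))
    if (v <= 0 || v >= 1) stopf("thresholds must lie in (0, 1)")
  structure(cfg, class = "fs_config")
}

#' Stratified train/test split
#'
#' Per class, assigns `round(ratio * n_c)` samples (clamped so that both
#' sides keep at least one sample) to the training set by seeded random
#' selection; the split is disjoint and exhaustive.
#'
#' @param labels per-sample class labels (each class needs >= 2 samples).
#' @param ratio training fraction.
#' @param seed integer seed.
#' @return list with integer `train` and `test` indices.
#' @export
stratified_split <- function(labels, ratio = 0.8, seed = 1) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < 2)) stopf("class(es) with < 2 samples: %s",
                          paste(names(tab)[tab < 2], collapse = ", "))
  with_seed(seed, {
    train <- integer(0)
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      n_tr <- min(max(round(ratio * length(idx)), 1), length(idx) - 1)
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Filter genes by correlation with case/control status
#'
#' Keeps genes whose absolute Pearson correlation (equivalently, the
#' point-biserial correlation) between expression and the 0/1 status
#' coding reaches `r_min`.  Constant genes have undefined correlation and
#' are dropped with a warning.
#'
#' @param x gene x sample matrix.
#' @param status per-sample case/control labels or 0/1.
#' @param genes gene ids to consider (default: all rows).
#' @param r_min minimum `|r|` (default 0.25).
#' @return character vector of surviving gene ids.
#' @export
correlation_filter <- function(x, status, genes = rownames(x), r_min = 0.25) {
  y <- status01(status)
  m <- x[genes, , drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    warnf("correlation_filter: dropping %d constant gene(s)", sum(sds == 0))
    m <- m[sds > 0, , drop = FALSE]
  }
  r <- as.numeric(stats::cor(t(m), y))
  rownames(m)[abs(r) >= r_min]
}

#' Greedy redundancy pruning of correlated genes
#'
#' Scans genes in priority order (best first); a gene is kept iff its
#' absolute Pearson correlation with every already-kept gene stays at or
#' below `r_max`, so each tightly correlated block contributes a single
#' representative — the statistically strongest one under the default
#' priority (ascending DE p-value).
#'
#' @param x gene x sample matrix.
#' @param genes candidate gene ids.
#' @param r_max pairwise threshold (default 0.8).
#' @param priority numeric vector aligned with `genes`; smaller = scanned
#'   first (default: input order). Ties break by gene id.
#' @return kept gene ids, in priority order.
#' @export
redundancy_prune <- function(x, genes, r_max = 0.8, priority = NULL) {
  if (length(genes) == 0) return(character(0))
  priority <- priority %||% seq_along(genes)
  ord <- order(priority, genes)
  genes <- genes[ord]
  if (length(genes) == 1) return(genes)
  cm <- abs(stats::cor(t(x[genes, , drop = FALSE])))
  kept <- logical(length(genes))
  for (i in seq_along(genes)) {
    if (!any(kept)) { kept[i] <- TRUE; next }
    if (all(cm[i, kept] <= r_max)) kept[i] <- TRUE
  }
  genes[kept]
}

#' Area under the ROC curve (tie-corrected rank statistic)
#'
#' @param scores numeric predictions (higher = more case-like).
#' @param labels case/control labels or 0/1 (case = positive).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- status01(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  r <- rank(scores)                       # midranks handle ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Interpolation-free summation over recall increments: thresholds sweep
#' the distinct score values from high to low and each recall step adds
#' `(R_i - R_{i-1}) * P_i`.  All-tied scores give the class prevalence.
#'
#' @inheritParams auroc
#' @return AUCPR in `[0, 1]`.
#' @export
aucpr <- function(scores, labels) {
  y <- status01(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  grp <- cumsum(!duplicated(s))           # tie groups share a threshold
  tp <- cumsum(y); n_seen <- seq_along(y)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; n_seen <- n_seen[last]
  recall <- tp / n1
  precision <- tp / n_seen
  sum(diff(c(0, recall)) * precision)
}

#' Univariate logistic-regression AUC for one gene
#'
#' Fits `status ~ expression` on the training samples (iteratively
#' reweighted least squares, tolerance 1e-8, up to 25 iterations) and
#' scores the held-out samples with the predicted probabilities, reporting
#' the test AUROC.  Under complete separation the probabilities are
#' replaced by the sign-oriented raw expression (AUROC is invariant to
#' monotone transforms).
#'
#' @param train_x,test_x gene x sample matrices.
#' @param train_y,test_y case/control labels; the test set must contain
#'   both classes.
#' @param gene gene id present in both matrices.
#' @return test AUROC.
#' @export
per_gene_auc <- function(train_x, train_y, test_x, test_y, gene) {
  y_tr <- status01(train_y); y_te <- status01(test_y)
  if (length(unique(y_te)) < 2) stopf("test set contains a single class")
  xt <- train_x[gene, ]; xs <- test_x[gene, ]
  fit <- suppressWarnings(stats::glm(
    y_tr ~ xt, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 25)))
  sep <- !fit$converged ||
    any(fit$fitted.values > 1 - 1e-10) || any(fit$fitted.values < 1e-10)
  scores <- if (sep) sign(stats::coef(fit)[2]) * xs else
    stats::predict(fit, newdata = data.frame(xt = xs), type = "response")
  auroc(scores, y_te)
}

# one tissue's per-iteration selection: training DE -> FDR gate ->
# status-correlation filter -> redundancy prune
select_tissue_iteration <- function(comp, split, cfg) {
  tr <- split$train
  ann <- comp$annotations[tr, , drop = FALSE]
  covars <- NULL
  use <- cfg$covariate_cols[cfg$covariate_cols %in% names(ann)]
  use <- use[vapply(use, function(cc) length(unique(ann[[cc]])) > 1, TRUE)]
  if (length(use)) covars <- ann[, use, drop = FALSE]
  de <- moderate_statistics(
    fit_linear_de(comp$values[, tr, drop = FALSE], ann$status, covars))
  sig <- de[de$p_adj < cfg$de_fdr, ]
  if (nrow(sig) == 0)
    return(list(genes = character(0), de = de))
  keep <- correlation_filter(comp$values[, tr, drop = FALSE], ann$status,
                             sig$gene_id, cfg$status_corr_min)
  sig <- sig[sig$gene_id %in% keep, ]
  pruned <- redundancy_prune(comp$values[, tr, drop = FALSE], sig$gene_id,
                             cfg$pairwise_corr_max, priority = sig$p)
  list(genes = pruned, de = de)
}

#' Iterative cross-tissue feature selection
#'
#' The resampling selection loop run jointly over two tissues restricted
#' to their common genes.  Each iteration draws independent stratified
#' 80:20 splits per tissue, identifies training-set significant genes
#' (moderated t, BH-adjusted p below `de_fdr`), applies the
#' status-correlation filter and redundancy pruning, intersects the two
#' tissues' selections while discarding genes called in opposite
#' directions, and measures each surviving gene's held-out AUROC (and
#' AUCPR) in both tissues via a univariate logistic model.  Genes present
#' in the intersection of every iteration are aggregated; the final set
#' keeps those whose mean test AUROC exceeds `auc_threshold` in both
#' tissues.
#'
#' @param tissue_a,tissue_b `compendium` objects (only case/control
#'   samples are used) sharing >= 100 genes.
#' @param cfg an [fs_config()].
#' @return object of class `fs_report`: per-iteration selections, overlap
#'   hypergeometric p-values, per-gene AUC summaries (mean +/- sd per
#'   tissue), the always-selected gene set, and the final feature-selected
#'   genes with their directions.
#' @export
run_feature_selection <- function(tissue_a, tissue_b, cfg = fs_config()) {
  stopifnot(inherits(tissue_a, "compendium"), inherits(tissue_b, "compendium"),
            inherits(cfg, "fs_config"))
  comps <- lapply(list(a = tissue_a, b = tissue_b), function(cc)
    subset_compendium(cc, samples = cc$annotations$status %in% c("case", "control")))
  common <- intersect(rownames(comps$a$values), rownames(comps$b$values))
  if (length(common) < 100) stopf("tissues share fewer than 100 genes")
  common <- sort(common)
  comps <- lapply(comps, subset_compendium, genes = common)

  iters <- vector("list", cfg$n_iterations)
  for (i in seq_len(cfg$n_iterations)) {
    seed_i <- cfg$base_seed + i
    sel <- list(); splits <- list()
    for (t in c("a", "b")) {
      comp <- comps[[t]]
      splits[[t]] <- stratified_split(comp$annotations$status,
                                      cfg$split_ratio,
                                      seed = seed_i + (t == "b") * 10000L)
      sel[[t]] <- select_tissue_iteration(comp, splits[[t]], cfg)
    }
    overlap <- intersect(sel$a$genes, sel$b$genes)
    p_overlap <- hypergeom_overlap_test(length(common),
                                        length(sel$a$genes),
                                        length(sel$b$genes), length(overlap))
    sign_a <- sel$a$de$logfc[match(overlap, sel$a$de$gene_id)]
    sign_b <- sel$b$de$logfc[match(overlap, sel$b$de$gene_id)]
    concordant <- overlap[sign(sign_a) == sign(sign_b)]
    discordant <- setdiff(overlap, concordant)

    auc <- list()
    for (t in c("a", "b")) {
      comp <- comps[[t]]; sp <- splits[[t]]
      y_tr <- comp$annotations$status[sp$train]
      y_te <- comp$annotations$status[sp$test]
      xtr <- comp$values[, sp$train, drop = FALSE]
      xte <- comp$values[, sp$test, drop = FALSE]
      auc[[t]] <- t(vapply(concordant, function(g) {
        y01tr <- status01(y_tr)
        fit <- suppressWarnings(stats::glm(
          y01tr ~ x, data = data.frame(x = xtr[g, ]),
          family = stats::binomial(),
          control = stats::glm.control(epsilon = 1e-8, maxit = 25)))
        sep <- !fit$converged || any(fit$fitted.values > 1 - 1e-10) ||
          any(fit$fitted.values < 1e-10)
        scores <- if (sep) sign(stats::coef(fit)[2]) * xte[g, ] else
          stats::predict(fit, newdata = data.frame(x = xte[g, ]),
                         type = "response")
        c(auroc = auroc(scores, y_te), aucpr = aucpr(scores, y_te))
      }, c(auroc = 0, aucpr = 0)))
    }
    dir_i <- ifelse(sign_a[match(concordant, overlap)] > 0, "up", "down")
    iters[[i]] <- list(seed = seed_i,
                       selected_a = sel$a$genes, selected_b = sel$b$genes,
                       concordant = concordant, discordant = discordant,
                       direction = stats::setNames(dir_i, concordant),
                       p_overlap = p_overlap,
                       auc_a = auc$a, auc_b = auc$b)
  }

  # genes present in the post-intersection set of every iteration
  always <- Reduce(intersect, lapply(iters, `[[`, "concordant"))
  summarize <- function(g, which_auc, col) {
    v <- vapply(iters, function(it) it[[which_auc]][g, col], 0)
    c(mean = mean(v), sd = stats::sd(v))
  }
  summary <- NULL
  if (length(always)) {
    summary <- do.call(rbind, lapply(always, function(g) {
      sa <- summarize(g, "auc_a", "auroc"); sb <- summarize(g, "auc_b", "auroc")
      pa <- summarize(g, "auc_a", "aucpr"); pb <- summarize(g, "auc_b", "aucpr")
      data.frame(gene_id = g,
                 direction = iters[[1]]$direction[[g]],
                 auc_a_mean = sa["mean"], auc_a_sd = sa["sd"],
                 auc_b_mean = sb["mean"], auc_b_sd = sb["sd"],
                 aucpr_a_mean = pa["mean"], aucpr_b_mean = pb["mean"],
                 stringsAsFactors = FALSE)
    }))
    rownames(summary) <- NULL
    final <- summary$gene_id[summary$auc_a_mean > cfg$auc_threshold &
                               summary$auc_b_mean > cfg$auc_threshold]
  } else final <- character(0)

  auc_pr_cor <- if (length(always) >= 3) c(
    tissue_a = suppressWarnings(stats::cor(summary$auc_a_mean, summary$aucpr_a_mean)),
    tissue_b = suppressWarnings(stats::cor(summary$auc_b_mean, summary$aucpr_b_mean)))
  else c(tissue_a = NA_real_, tissue_b = NA_real_)

  structure(list(config = cfg, universe = common, iterations = iters,
                 always_selected = always, summary = summary,
                 final_genes = final,
                 final_directions = if (!is.null(summary))
                   stats::setNames(summary$direction, summary$gene_id)[final]
                 else character(0),
                 auroc_aucpr_cor = auc_pr_cor),
            class = "fs_report")
}

#' @export
#' @method print fs_report
print.fs_report <- function(x, ...) {
  cat(sprintf("fs_report: %d iterations over %d common genes\n",
              length(x$iterations), length(x$universe)))
  cat(sprintf("  always selected: %d genes; final (AUC > %.3f in both tissues): %d\n",
              length(x$always_selected), x$config$auc_threshold,
              length(x$final_genes)))
  invisible(x)
}
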