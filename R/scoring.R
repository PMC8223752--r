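#' Per-gene validation on independent cohorts
#'
#' For each candidate gene, a univariate logistic model is fitted once on
#' the (z-scaled) discovery data and applied unchanged to every (z-scaled)
#' validation cohort; the per-cohort AUROCs are averaged and genes whose
#' mean exceeds `auc_min` form the panel, split into up/down lists by the
#' sign of the discovery log2 fold-change.  Candidates absent from any
#' validation set are excluded from candidacy with a warning, and a
#' validation set containing a single class is skipped for all genes.
#'
#' @param discovery `compendium` of case/control discovery samples
#'   (z-scaled per gene; see [zscale_genes()]).
#' @param validation_sets list of z-scaled `compendium` objects.
#' @param candidate_genes character vector of candidate gene ids.
#' @param auc_min mean validation AUROC threshold (default 0.8).
#' @param directions optional named vector ("up"/"down") per candidate;
#'   recomputed from a discovery DE fit when omitted.
#' @return object of class `score_panel`: `up_genes`, `down_genes`, and a
#'   per-gene table of discovery and mean validation AUROCs.
#' @export
validate_genes <- function(discovery, validation_sets, candidate_genes,
                           auc_min = 0.8, directions = NULL) {
  stopifnot(inherits(discovery, "compendium"))
  keep <- vapply(candidate_genes, function(g)
    all(vapply(validation_sets, function(v) g %in% rownames(v$values), TRUE)),
    TRUE)
  if (any(!keep))
    warnf("validate_genes: %d candidate(s) absent from some validation set, dropped: %s",
          sum(!keep), paste(utils::head(candidate_genes[!keep], 10), collapse = ", "))
  candidates <- candidate_genes[keep]
  if (length(candidates) == 0) stopf("no candidates present in all validation sets")

  y_disc <- status01(discovery$annotations$status)
  if (is.null(directions)) {
    de <- fit_linear_de(discovery)
    directions <- stats::setNames(ifelse(de$logfc > 0, "up", "down"), de$genes)
  }
  usable <- vapply(validation_sets, function(v)
    length(unique(v$annotations$status)) >= 2, TRUE)
  if (any(!usable))
    warnf("validate_genes: %d single-class validation set(s) skipped", sum(!usable))
  vsets <- validation_sets[usable]
  if (length(vsets) == 0) stopf("no usable validation sets")

  rows <- lapply(candidates, function(g) {
    xg <- discovery$values[g, ]
    fit <- suppressWarnings(stats::glm(y_disc ~ xg, family = stats::binomial()))
    disc_auc <- auroc(stats::fitted(fit), y_disc)
    val_auc <- vapply(vsets, function(v) {
      sc <- stats::coef(fit)[1] + stats::coef(fit)[2] * v$values[g, ]
      auroc(sc, v$annotations$status)
    }, 0)
    data.frame(gene_id = g, direction = unname(directions[g]),
               discovery_auc = disc_auc,
               validation_auc = mean(val_auc), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  sel <- tab[tab$validation_auc > auc_min, ]
  structure(list(up_genes = sel$gene_id[sel$direction == "up"],
                 down_genes = sel$gene_id[sel$direction == "down"],
                 table = tab, auc_min = auc_min),
            class = "score_panel")
}

#' @export
#' @method print score_panel
print.score_panel <- function(x, ...) {
  cat(sprintf("score_panel: %d up, %d down (mean validation AUC > %.2f)\n",
              length(x$up_genes), length(x$down_genes), x$auc_min))
  invisible(x)
}

#' Compare gene-set classifiers on independent cohorts
#'
#' Trains, per gene set, three multivariate classifiers — logistic
#' regression, elastic-net logistic regression (mixing 0.5, penalty by
#' internal 5-fold cross-validation on the discovery data only) and a
#' random forest (500 trees) — once on the discovery data, then applies
#' each fixed model to every validation cohort and reports the per-set
#' AUROC with its mean and standard error.  Overlapping sample ids
#' between discovery and validation are rejected as a leakage guard.
#'
#' @param discovery `compendium` (z-scaled recommended).
#' @param validation_sets list of `compendium` objects.
#' @param gene_sets named list of gene-id vectors (duplicates are removed
#'   with a warning; sets are reduced to genes shared with all cohorts).
#' @param models subset of `c("logistic", "elastic_net", "random_forest")`.
#' @param seed seed for the cross-validation folds and forest.
#' @return data.frame `gene_set, model, mean_auc, se_auc` plus per-cohort
#'   columns.
#' @export
compare_gene_sets <- function(discovery, validation_sets, gene_sets,
                              models = c("logistic", "elastic_net",
                                         "random_forest"),
                              seed = 1) {
  models <- match.arg(models, several.ok = TRUE)
  disc_ids <- colnames(discovery$values)
  for (v in validation_sets)
    if (length(intersect(disc_ids, colnames(v$values))))
      stopf("validation set shares sample ids with discovery (leakage guard)")
  y <- status01(discovery$annotations$status)

  out <- list()
  for (nm in names(gene_sets)) {
    gs <- gene_sets[[nm]]
    if (anyDuplicated(gs)) {
      warnf("gene set '%s': duplicates removed", nm)
      gs <- unique(gs)
    }
    shared <- Reduce(intersect, c(list(gs, rownames(discovery$values)),
                                  lapply(validation_sets,
                                         function(v) rownames(v$values))))
    if (length(shared) == 0) stopf("gene set '%s' empty after reduction", nm)
    xtr <- t(discovery$values[shared, , drop = FALSE])
    fits <- with_seed(seed, {
      f <- list()
      if ("logistic" %in% models)
        f$logistic <- suppressWarnings(
          stats::glm(y ~ ., data = data.frame(xtr), family = stats::binomial()))
      if ("elastic_net" %in% models)
        f$elastic_net <- glmnet::cv.glmnet(xtr, y, family = "binomial",
                                           alpha = 0.5, nfolds = 5)
      if ("random_forest" %in% models)
        f$random_forest <- randomForest::randomForest(
          xtr, factor(y, levels = c(0, 1)), ntree = 500)
      f
    })
    for (mdl in names(fits)) {
      aucs <- vapply(seq_along(validation_sets), function(i) {
        v <- validation_sets[[i]]
        xte <- t(v$values[shared, , drop = FALSE])
        sc <- switch(mdl,
          logistic = stats::predict(fits$logistic,
                                    newdata = data.frame(xte),
                                    type = "response"),
          elastic_net = as.numeric(stats::predict(fits$elastic_net, xte,
                                                  s = "lambda.min",
                                                  type = "response")),
          random_forest = stats::predict(fits$random_forest, xte,
                                         type = "prob")[, "1"])
        auroc(sc, v$annotations$status)
      }, 0)
      out[[length(out) + 1]] <- data.frame(
        gene_set = nm, model = mdl, n_genes = length(shared),
        mean_auc = mean(aucs),
        se_auc = stats::sd(aucs) / sqrt(length(aucs)),
        t(stats::setNames(aucs, sprintf("auc_set%d", seq_along(aucs)))),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Composite disease score: difference of geometric means
#'
#' Per sample, the score is the geometric mean of the up-regulated panel
#' genes minus the geometric mean of the down-regulated ones, with the
#' geometric means taken on the linear scale (`2^x` for log2 input):
#' `GM = 2^(mean of log2 values)`.  The score is computed from log2
#' expression, never from z-scaled data (geometric means require
#' positivity).  Panel genes absent from the matrix are dropped with a
#' warning, so the score degrades gracefully when a gene is unavailable.
#'
#' @param x gene x sample matrix on the log2 scale (or `compendium`).
#' @param panel a `score_panel`, or a list with `up_genes`/`down_genes`.
#' @return named numeric vector of per-sample scores.
#' @export
ra_score <- function(x, panel) {
  if (inherits(x, "compendium")) x <- x$values
  check_numeric_matrix(x, "x")
  up <- intersect(panel$up_genes, rownames(x))
  down <- intersect(panel$down_genes, rownames(x))
  n_missing <- length(panel$up_genes) + length(panel$down_genes) -
    length(up) - length(down)
  if (n_missing > 0)
    warnf("ra_score: %d panel gene(s) absent from the matrix, dropped", n_missing)
  if (length(up) == 0 || length(down) == 0)
    stopf("panel must contribute at least one up and one down gene")
  gm_up <- 2^colMeans(x[up, , drop = FALSE])
  gm_down <- 2^colMeans(x[down, , drop = FALSE])
  gm_up - gm_down
}

#' Group effect of the score: ratio of means and t-test
#'
#' @param scores named per-sample scores.
#' @param groups per-sample group labels (exactly 2 groups used: the first
#'   level is the numerator of the mean ratio).
#' @param paired optional per-sample pair ids; when supplied, a paired t
#'   test over complete pairs replaces the Welch test.
#' @return list with `ratio` (mean of group 1 / mean of group 2; `NA` with
#'   a warning when the denominator mean is not positive), `p`, group
#'   means and sizes.
#' @export
score_group_effect <- function(scores, groups, paired = NULL) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stopf("exactly 2 groups required, got %d", length(lev))
  g1 <- scores[groups == lev[1]]; g2 <- scores[groups == lev[2]]
  if (length(g1) < 2 || length(g2) < 2) stopf("each group needs >= 2 samples")
  if (!is.null(paired)) {
    p1 <- paired[groups == lev[1]]; p2 <- paired[groups == lev[2]]
    common <- intersect(p1[p1 != ""], p2[p2 != ""])
    if (length(common) < 2) stopf("fewer than 2 complete pairs")
    tt <- stats::t.test(g1[match(common, p1)], g2[match(common, p2)],
                        paired = TRUE)
  } else {
    tt <- stats::t.test(g1, g2)
  }
  m1 <- mean(g1); m2 <- mean(g2)
  ratio <- if (m2 <= 0) {
    warnf("score_group_effect: non-positive denominator mean; ratio = NA")
    NA_real_
  } else m1 / m2
  list(ratio = ratio, p = tt$p.value,
       means = stats::setNames(c(m1, m2), lev),
       n = stats::setNames(c(length(g1), length(g2)), lev))
}

#' Correlation of the score with disease activity (DAS28)
#'
#' Pearson correlation per dataset, pooled as the sample-size-weighted
#' mean with a stratified-bootstrap percentile 95% confidence interval.
#' Datasets with constant DAS28 or fewer than 3 annotated samples are
#' skipped with a warning.
#'
#' @param scores per-sample scores.
#' @param das28 per-sample DAS28 values (`NA` = unannotated).
#' @param dataset_labels per-sample dataset of origin.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed bootstrap seed.
#' @return list with `per_dataset` (data.frame `dataset, n, r, p`),
#'   `pooled_r`, `ci` and `fisher_p` (Fisher-combined per-dataset p).
#' @export
score_das28_correlation <- function(scores, das28, dataset_labels,
                                    n_boot = 1000, seed = 1) {
  keep <- !is.na(das28)
  scores <- scores[keep]; das28 <- das28[keep]
  dataset_labels <- as.character(dataset_labels)[keep]
  rows <- list(); boot_data <- list()
  for (ds in unique(dataset_labels)) {
    idx <- dataset_labels == ds
    if (sum(idx) < 3) { warnf("dataset '%s': < 3 annotated samples, skipped", ds); next }
    if (stats::sd(das28[idx]) == 0) {
      warnf("dataset '%s': constant DAS28, skipped", ds); next
    }
    ct <- stats::cor.test(scores[idx], das28[idx])
    rows[[ds]] <- data.frame(dataset = ds, n = sum(idx),
                             r = unname(ct$estimate), p = ct$p.value,
                             stringsAsFactors = FALSE)
    boot_data[[ds]] <- list(s = scores[idx], d = das28[idx])
  }
  if (length(rows) == 0) stopf("no dataset usable for DAS28 correlation")
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  w <- tab$n / sum(tab$n)
  pooled <- sum(w * tab$r)
  ci <- with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(b) {
      rs <- vapply(boot_data, function(bd) {
        i <- sample(length(bd$s), replace = TRUE)
        suppressWarnings(stats::cor(bd$s[i], bd$d[i]))
      }, 0)
      sum(w * rs)
    }, 0)
    stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  })
  # exact-zero p from perfect correlations is floored before combining
  list(per_dataset = tab, pooled_r = pooled, ci = ci,
       fisher_p = fisher_combine(pmax(tab$p, .Machine$double.xmin)))
}

#' Fisher's method for combining p-values
#'
#' `X = -2 * sum(log p_i)` referred to a chi-square distribution on `2k`
#' degrees of freedom.
#'
#' @param pvals p-values in `(0, 1]`; a zero p-value is an error (floor it
#'   at machine epsilon explicitly if that is intended).
#' @return combined p-value.
#' @export
fisher_combine <- function(pvals) {
  if (length(pvals) == 0) stopf("no p-values supplied")
  if (any(pvals <= 0 | pvals > 1))
    stopf("p-values must lie in (0, 1]; floor zeros at .Machine$double.eps explicitly")
  stats::pchisq(-2 * sum(log(pvals)), df = 2 * length(pvals),
                lower.tail = FALSE)
}

#' Bootstrap odds ratio of class on the standardized score
#'
#' Logistic regression of the binary contrast on the per-dataset
#' standardized score; the odds ratio is per 1 SD of score and the first
#' listed contrast class is the outcome.  Samples are bootstrapped
#' stratified within dataset; with several datasets the per-dataset odds
#' ratios are pooled by the bootstrap mean.  The p-value is the normal
#' tail of the bootstrap log-OR distribution against zero.
#'
#' @param scores per-sample scores.
#' @param labels per-sample class labels.
#' @param contrast length-2 character: `c(outcome_class, reference_class)`;
#'   samples outside the contrast are ignored.  Each class needs >= 5
#'   samples.
#' @param dataset_labels optional per-sample dataset labels (default: one
#'   dataset).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed bootstrap seed.
#' @param cap absolute cap on the fitted log-OR under complete separation.
#' @return list with `or`, `ci` (percentile 95%), `p`, `capped` flag.
#' @export
bootstrap_or <- function(scores, labels, contrast, dataset_labels = NULL,
                         n_boot = 1000, seed = 1, cap = log(1e3)) {
  labels <- as.character(labels)
  keep <- labels %in% contrast
  scores <- scores[keep]; labels <- labels[keep]
  dataset_labels <- if (is.null(dataset_labels)) rep("all", sum(keep)) else
    as.character(dataset_labels)[keep]
  if (any(table(labels) < 5)) stopf("each contrast class needs >= 5 samples")
  y <- as.integer(labels == contrast[1])

  fit_logor <- function(s, yy) {
    if (length(unique(yy)) < 2 || stats::sd(s) == 0) return(NA_real_)
    z <- (s - mean(s)) / stats::sd(s)
    fit <- suppressWarnings(stats::glm(yy ~ z, family = stats::binomial()))
    b <- stats::coef(fit)[2]
    if (!is.finite(b)) return(NA_real_)
    max(min(b, cap), -cap)
  }
  per_ds_logor <- function(s, yy, ds) {
    v <- vapply(unique(ds), function(d)
      fit_logor(s[ds == d], yy[ds == d]), 0)
    mean(v, na.rm = TRUE)
  }
  point <- per_ds_logor(scores, y, dataset_labels)
  capped <- abs(point) >= cap - 1e-9
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- unlist(lapply(unique(dataset_labels), function(d) {
      i <- which(dataset_labels == d)
      sample(i, replace = TRUE)
    }))
    per_ds_logor(scores[idx], y[idx], dataset_labels[idx])
  }, 0))
  boots <- boots[is.finite(boots)]
  ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  se <- stats::sd(boots)
  p <- if (se == 0) NA_real_ else 2 * stats::pnorm(-abs(point) / se)
  list(or = exp(point), ci = exp(ci), p = p, capped = capped,
       log_or = point)
}

#' Random-panel null distribution for the score
#'
#' Repeatedly draws random panels of the same up/down split sizes
#' (excluding the true panel genes), computes each random panel's score
#' and its Pearson correlation with the outcome, and compares the true
#' panel's correlation with the null by a two-sided one-sample t-test.
#'
#' @param x gene x sample log2 matrix (or `compendium`).
#' @param panel the true `score_panel` (also defines the split sizes).
#' @param outcome per-sample numeric outcome (e.g. DAS28); `NA` dropped.
#' @param n_iter random panels (default 100).
#' @param seed integer seed.
#' @return list with `null_r` (vector), `true_r`, `p`.
#' @export
random_panel_null <- function(x, panel, outcome, n_iter = 100, seed = 1) {
  if (inherits(x, "compendium")) x <- x$values
  n_up <- length(panel$up_genes); n_down <- length(panel$down_genes)
  pool <- setdiff(rownames(x), c(panel$up_genes, panel$down_genes))
  if (length(pool) < n_up + n_down)
    stopf("not enough genes outside the panel to draw random panels")
  keep <- !is.na(outcome)
  xk <- x[, keep, drop = FALSE]; out <- outcome[keep]
  true_r <- stats::cor(ra_score(xk, panel), out)
  null_r <- with_seed(seed, vapply(seq_len(n_iter), function(i) {
    g <- sample(pool, n_up + n_down)
    rp <- list(up_genes = g[seq_len(n_up)], down_genes = g[-seq_len(n_up)])
    stats::cor(ra_score(xk, rp), out)
  }, 0))
  tt <- stats::t.test(null_r, mu = true_r)
  list(null_r = null_r, true_r = true_r, p = tt$p.value,
       null_mean = mean(null_r))
}
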