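#' Gene-wise linear model for a case/control contrast
#'
#' Fits, per gene, an ordinary least-squares model of expression on the
#' case/control status plus optional covariates (e.g. sex and treatment
#' category, each encoded as indicators against a reference level).  The
#' design is shared by all genes, so the fit is a single QR decomposition.
#'
#' @param x numeric gene x sample matrix (log2 scale) or `compendium`.
#' @param status per-sample labels, `"case"`/`"control"` (or 0/1 with
#'   case = 1).  Taken from the annotations when `x` is a compendium.
#' @param covariates optional per-sample data.frame of covariates;
#'   character columns are treated as factors (first level = reference).
#' @return list of class `de_fit`: per-gene coefficient (`logfc`, the
#'   case - control contrast), `stdev_unscaled` (common to all genes),
#'   residual variance `s2`, residual `df`, and the design used.
#' @export
fit_linear_de <- function(x, status = NULL, covariates = NULL) {
  if (inherits(x, "compendium")) {
    status <- status %||% x$annotations$status
    x <- x$values
  }
  check_numeric_matrix(x, "x")
  y01 <- status01(status)
  if (length(y01) != ncol(x)) stopf("status must have one label per sample")
  if (min(table(y01)) < 2) stopf("need >= 2 samples in each status class")

  df_design <- data.frame(status = y01)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
    for (nm in names(covariates)) {
      if (is.character(covariates[[nm]])) covariates[[nm]] <- factor(covariates[[nm]])
      df_design[[nm]] <- covariates[[nm]]
    }
  }
  X <- stats::model.matrix(~ ., data = df_design)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stopf("rank-deficient design; aliased columns: %s",
          paste(aliased, collapse = ", "))
  }
  fit <- stats::lm.fit(X, t(x))
  coefs <- fit$coefficients
  df_resid <- ncol(x) - ncol(X)
  if (df_resid < 1) stopf("no residual degrees of freedom")
  rss <- colSums(fit$residuals^2)
  s2 <- rss / df_resid
  xtx_inv <- chol2inv(qr.R(qrX))
  su <- sqrt(xtx_inv[2, 2])      # unscaled sd of the status coefficient
  zero_var <- s2 <= .Machine$double.eps * 100
  structure(list(
    genes = rownames(x),
    logfc = unname(coefs["status", ]),
    stdev_unscaled = su,
    s2 = unname(s2), df = df_resid,
    zero_variance = rownames(x)[zero_var],
    design_columns = colnames(X)), class = "de_fit")
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' Shrinks per-gene residual variances toward a common prior estimated
#' from the whole ensemble by moment matching on the log variances:
#' the prior degrees of freedom `d0` solve a trigamma equation and the
#' prior variance `s0^2` follows from the matched mean.  The posterior
#' variance is `(d0*s0^2 + d*s2) / (d0 + d)` and the moderated t is
#' referred to a t distribution on `d0 + d` degrees of freedom
#' (a normal reference when `d0` is infinite).
#'
#' @param fit a `de_fit` from [fit_linear_de()] (>= 10 genes).
#' @param d0 optional prior df override (e.g. `0` for ordinary t,
#'   `Inf` for full shrinkage); estimated from the data when `NULL`.
#' @return data.frame of class `de_result`: `gene_id, logfc, se, t_mod,
#'   p, p_adj, direction`, with the hyperparameters in attributes
#'   `d0` and `s02`.
#' @export
moderate_statistics <- function(fit, d0 = NULL) {
  stopifnot(inherits(fit, "de_fit"))
  s2 <- fit$s2
  if (length(s2) < 10) stopf("need >= 10 genes to estimate hyperparameters")
  if (any(!is.finite(s2))) stopf("non-finite residual variances")
  d <- fit$df

  est <- estimate_variance_prior(s2, d)
  if (!is.null(d0)) est$d0 <- d0
  d0 <- est$d0; s02 <- est$s02

  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
    else if (d0 == 0) s2
    else (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(s2_post) * fit$stdev_unscaled
  t_mod <- fit$logfc / se
  df_total <- d0 + d
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t_mod)) else
    2 * stats::pt(-abs(t_mod), df = df_total)
  p_adj <- bh_adjust(p)
  res <- data.frame(
    gene_id = fit$genes, logfc = fit$logfc, se = se, t_mod = t_mod,
    df = df_total, p = p, p_adj = p_adj,
    direction = ifelse(p_adj < 0.05 & fit$logfc > log2(1.2), "up",
                ifelse(p_adj < 0.05 & fit$logfc < -log2(1.2), "down", "ns")),
    stringsAsFactors = FALSE)
  attr(res, "d0") <- d0
  attr(res, "s02") <- s02
  class(res) <- c("de_result", "data.frame")
  res
}

# moment matching of log s2 against the scaled-F model; returns the
# prior df d0 and prior variance s02 (d0 = Inf when the excess variance
# of log s2 is non-positive)
estimate_variance_prior <- function(s2, d) {
  ok <- s2 > 0
  if (!any(ok)) stopf("all residual variances are zero")
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  e_bar <- mean(e)
  excess <- mean((e - e_bar)^2 * length(e) / (length(e) - 1)) - trigamma(d / 2)
  if (is.na(excess) || excess <= 0)
    return(list(d0 = Inf, s02 = exp(e_bar)))
  d0 <- 2 * trigamma_inverse(excess)
  s02 <- exp(e_bar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with cumulative-minimum
#' enforcement; a thin, range-checked wrapper over [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' Applies the joint significance / effect-size gate: `p_adj < fdr` and a
#' fold change beyond `fc` on the ratio scale (i.e. `|log2FC| > log2(fc)`;
#' down-regulation corresponds to fold changes below `1/fc`).
#'
#' @param de a `de_result` from [moderate_statistics()].
#' @param fdr adjusted-p threshold (default 0.05).
#' @param fc fold-change threshold on the ratio scale (default 1.2, must
#'   exceed 1).
#' @return list with `up` and `down` gene-id vectors.
#' @export
call_de <- function(de, fdr = 0.05, fc = 1.2) {
  stopifnot(inherits(de, "de_result"))
  if (fc <= 1) stopf("fc must exceed 1")
  lfc <- log2(fc)
  sig <- de$p_adj < fdr
  list(up = de$gene_id[sig & de$logfc > lfc],
       down = de$gene_id[sig & de$logfc < -lfc])
}

#' Upper-tail hypergeometric overlap test
#'
#' P(X >= k) when `k` of the `n` drawn genes fall in a marked set of size
#' `K` out of a universe of `N`; evaluated through the stable log-scale
#' tail of the hypergeometric distribution.
#'
#' @param N universe size; `K` marked genes; `n` drawn genes; `k` observed
#'   overlap, with `0 <= k <= min(K, n) <= N`.
#' @return the upper-tail p-value.
#' @export
hypergeom_overlap_test <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n))
    stopf("inconsistent hypergeometric counts (N=%s, K=%s, n=%s, k=%s)",
          N, K, n, k)
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Cross-tissue concordance of differential-expression calls
#'
#' Intersects the up/down calls of two tissues, separates concordant from
#' discordant genes, and attaches per-direction hypergeometric overlap
#' p-values computed against the common-gene background with the full
#' per-tissue call counts (K = up calls in A, n = up calls in B,
#' k = their overlap, and likewise for down).
#'
#' @param de_a,de_b `de_result` objects on overlapping gene universes.
#' @param background_n size of the common-gene background.
#' @param fdr,fc thresholds passed to [call_de()].
#' @return list with `up`, `down` (concordant ids), `discordant`,
#'   per-direction hypergeometric parameters and p-values.
#' @export
cross_tissue_overlap <- function(de_a, de_b, background_n,
                                 fdr = 0.05, fc = 1.2) {
  a <- call_de(de_a, fdr, fc)
  b <- call_de(de_b, fdr, fc)
  all_called <- unique(c(a$up, a$down, b$up, b$down))
  if (background_n < length(all_called))
    stopf("background_n (%d) smaller than the union of called sets (%d)",
          background_n, length(all_called))
  up <- intersect(a$up, b$up)
  down <- intersect(a$down, b$down)
  discordant <- union(intersect(a$up, b$down), intersect(a$down, b$up))
  p_up <- hypergeom_overlap_test(background_n, length(a$up),
                                 length(b$up), length(up))
  p_down <- hypergeom_overlap_test(background_n, length(a$down),
                                   length(b$down), length(down))
  list(up = up, down = down, discordant = discordant,
       params_up = c(N = background_n, K = length(a$up),
                     n = length(b$up), k = length(up)),
       params_down = c(N = background_n, K = length(a$down),
                       n = length(b$down), k = length(down)),
       p_up = p_up, p_down = p_down)
}

#' Over-representation analysis against user-supplied gene sets
#'
#' Generic hypergeometric enrichment of a query set in each collection
#' set, restricted to the supplied background, with BH adjustment across
#' collections.
#'
#' @param query_set character vector of gene ids (must lie within
#'   `background`).
#' @param collections named list of gene-id vectors (e.g. read from a GMT
#'   file).
#' @param background character vector: the gene universe.
#' @return data.frame `set, N, K, n, k, p, p_adj` sorted by `p`.
#' @export
ora <- function(query_set, collections, background) {
  if (length(background) == 0) stopf("empty background")
  if (length(collections) == 0) stopf("empty collections")
  if (!all(query_set %in% background))
    stopf("query_set must be a subset of background")
  N <- length(unique(background))
  q <- unique(query_set)
  rows <- lapply(names(collections), function(nm) {
    set <- intersect(unique(collections[[nm]]), background)
    k <- length(intersect(q, set))
    data.frame(set = nm, N = N, K = length(set), n = length(q), k = k,
               p = hypergeom_overlap_test(N, length(set), length(q), k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out[order(out$p), ]
}
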