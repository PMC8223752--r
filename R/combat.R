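#' Empirical-Bayes location/scale batch adjustment
#'
#' Parametric empirical-Bayes adjustment of a merged expression matrix for
#' known batches (datasets of origin), in the classical location/scale
#' formulation: genes are standardized against the batch-size-weighted
#' grand mean and pooled variance, per-batch per-gene location and scale
#' estimates are shrunk toward normal / inverse-gamma priors by the
#' iterative EB update, and the data are back-transformed with the grand
#' structure restored.  An optional covariate design is protected (its
#' fitted effects are kept in the standardization mean and restored).
#'
#' @param x numeric gene x sample matrix, or a `compendium` (whose
#'   `dataset` annotation then supplies `batch`).
#' @param batch per-sample batch labels; every batch needs >= 2 samples and
#'   there must be >= 2 batches unless `allow_single_batch = TRUE` (in
#'   which case the input is returned essentially unchanged).
#' @param covariates optional per-sample data.frame of biological
#'   covariates to protect; must not be confounded with batch.
#' @param conv relative-change convergence tolerance of the EB iteration.
#' @param max_iter maximum EB iterations per batch.
#' @param allow_single_batch disable the >= 2 batch guard.
#' @return list with `values` (adjusted matrix, or adjusted `compendium`
#'   when one was supplied) and `model` (per-batch location/scale
#'   estimates, EB hyperparameters, grand mean and pooled variance —
#'   sufficient to reproduce the adjustment exactly).
#' @export
combat_adjust <- function(x, batch = NULL, covariates = NULL,
                          conv = 1e-4, max_iter = 100,
                          allow_single_batch = FALSE) {
  comp <- NULL
  if (inherits(x, "compendium")) {
    comp <- x
    batch <- batch %||% comp$annotations$dataset
    x <- comp$values
  }
  check_numeric_matrix(x, "x")
  if (is.null(batch) || length(batch) != ncol(x))
    stopf("`batch` must have one label per sample")
  batch <- factor(batch)
  nb <- nlevels(batch)
  n_arr <- ncol(x)
  sizes <- table(batch)
  if (any(sizes < 2))
    stopf("batch(es) with a single sample: %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  if (nb < 2) {
    if (!allow_single_batch)
      stopf("need >= 2 batches (set allow_single_batch = TRUE to bypass)")
    # one batch: nothing to adjust
    model <- list(batch_levels = levels(batch),
                  batch_sizes = as.integer(sizes),
                  gamma_star = matrix(0, nrow(x), 1),
                  delta_star = matrix(1, nrow(x), 1))
    if (!is.null(comp)) return(list(values = comp, model = model))
    return(list(values = x, model = model))
  }

  batch_design <- stats::model.matrix(~ 0 + batch)
  colnames(batch_design) <- levels(batch)
  design <- batch_design
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    cov_mm <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
    design <- cbind(batch_design, cov_mm)
    qr_d <- qr(design)
    if (qr_d$rank < ncol(design)) {
      aliased <- colnames(design)[qr_d$pivot[-seq_len(qr_d$rank)]]
      stopf("covariate design confounded with batch; aliased columns: %s",
            paste(aliased, collapse = ", "))
    }
  }

  # gene-wise least squares on the full design; grand mean = batch-size
  # weighted combination of batch intercepts
  B_hat <- solve(crossprod(design), crossprod(design, t(x)))
  grand_mean <- crossprod(as.numeric(sizes) / n_arr,
                          B_hat[seq_len(nb), , drop = FALSE])
  var_pooled <- rowSums((x - t(design %*% B_hat))^2) / n_arr
  if (any(var_pooled <= 0)) stopf("gene(s) with zero pooled variance")

  stand_mean <- matrix(grand_mean, nrow(x), n_arr)
  if (!is.null(covariates)) {
    tmp <- design
    tmp[, seq_len(nb)] <- 0
    stand_mean <- stand_mean + t(tmp %*% B_hat)
  }
  s_data <- (x - stand_mean) / sqrt(var_pooled)

  # per-batch location/scale estimates on the standardized data
  gamma_hat <- t(solve(crossprod(batch_design),
                       crossprod(batch_design, t(s_data))))   # genes x batches
  delta_hat <- sapply(levels(batch), function(b)
    apply(s_data[, batch == b, drop = FALSE], 1, stats::var))

  # EB hyperparameters (moment estimators of the normal / inverse-gamma priors)
  gamma_bar <- colMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 2, stats::var)
  a_prior <- apply(delta_hat, 2, function(d) {
    m <- mean(d); s2 <- stats::var(d)
    if (s2 == 0) return(Inf)
    (2 * s2 + m^2) / s2 })
  b_prior <- apply(delta_hat, 2, function(d) {
    m <- mean(d); s2 <- stats::var(d)
    if (s2 == 0) return(Inf)
    (m * s2 + m^3) / s2 })

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (i in seq_len(nb)) {
    idx <- batch == levels(batch)[i]
    n_i <- sum(idx)
    g_old <- gamma_hat[, i]; d_old <- delta_hat[, i]
    sdat <- s_data[, idx, drop = FALSE]
    if (!is.finite(a_prior[i])) {
      # degenerate scale ensemble: prior infinitely concentrated at its mean
      d_fix <- rep(mean(delta_hat[, i]), nrow(x))
      gamma_star[, i] <- (n_i * tau2[i] * gamma_hat[, i] + d_fix * gamma_bar[i]) /
        (n_i * tau2[i] + d_fix)
      delta_star[, i] <- d_fix
      next
    }
    for (it in seq_len(max_iter)) {
      # posterior mean always conditions on the observed batch effect
      # estimate; only the scale posterior feeds back into the iteration
      g_new <- (n_i * tau2[i] * gamma_hat[, i] + d_old * gamma_bar[i]) /
        (n_i * tau2[i] + d_old)
      sum2 <- rowSums((sdat - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[i]) / (n_i / 2 + a_prior[i] - 1)
      change <- max(abs(g_new - g_old) / abs(g_old + 1e-12),
                    abs(d_new - d_old) / d_old)
      g_old <- g_new; d_old <- d_new
      if (change < conv) break
    }
    gamma_star[, i] <- g_old
    delta_star[, i] <- d_old
  }

  adjusted <- s_data
  for (i in seq_len(nb)) {
    idx <- batch == levels(batch)[i]
    adjusted[, idx] <- (s_data[, idx, drop = FALSE] - gamma_star[, i]) /
      sqrt(delta_star[, i])
  }
  adjusted <- adjusted * sqrt(var_pooled) + stand_mean
  dimnames(adjusted) <- dimnames(x)

  model <- list(batch_levels = levels(batch), batch_sizes = as.integer(sizes),
                gamma_hat = gamma_hat, delta_hat = delta_hat,
                gamma_star = gamma_star, delta_star = delta_star,
                gamma_bar = gamma_bar, tau2 = tau2,
                a_prior = a_prior, b_prior = b_prior,
                grand_mean = as.numeric(grand_mean), var_pooled = var_pooled)
  if (!is.null(comp)) {
    comp$values <- adjusted
    comp$flags$batch_adjusted <- TRUE
    return(list(values = comp, model = model))
  }
  list(values = adjusted, model = model)
}
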