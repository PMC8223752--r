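# Independent oracles used to cross-check the package implementations.
# These are written straight from first principles (loops, enumeration,
# closed forms) and deliberately share no code with R/.

# AUROC by exhaustive pair counting (ties count 1/2)
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  total / (length(pos) * length(neg))
}

# upper-tail hypergeometric by direct summation of combinatorial terms
oracle_hyper_tail <- function(N, K, n, k) {
  if (k == 0) return(1)
  tot <- 0
  for (i in k:min(K, n))
    tot <- tot + choose(K, i) * choose(N - K, n - i)
  tot / choose(N, n)
}

# BH step-up applied literally: sort, scale, cumulative minimum from the top
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# straight-line parametric EB batch adjustment (no covariates), coded
# gene-by-gene from the published location/scale model
oracle_combat <- function(x, batch, conv = 1e-10, max_iter = 5000) {
  batch <- factor(batch)
  levs <- levels(batch)
  G <- nrow(x); n <- ncol(x)
  sizes <- sapply(levs, function(b) sum(batch == b))

  # gene-wise batch means, grand mean, pooled variance
  bmeans <- sapply(levs, function(b) rowMeans(x[, batch == b, drop = FALSE]))
  grand <- as.numeric(bmeans %*% (sizes / n))
  fitted <- matrix(0, G, n)
  for (b in levs) fitted[, batch == b] <- bmeans[, b]
  varp <- rowSums((x - fitted)^2) / n

  z <- (x - grand) / sqrt(varp)
  g_hat <- sapply(levs, function(b) rowMeans(z[, batch == b, drop = FALSE]))
  d_hat <- sapply(levs, function(b) apply(z[, batch == b, drop = FALSE], 1, var))

  g_bar <- colMeans(g_hat)
  t2 <- apply(g_hat, 2, var)
  a_pr <- sapply(levs, function(b) {
    m <- mean(d_hat[, b]); s2 <- var(d_hat[, b]); (2 * s2 + m^2) / s2 })
  b_pr <- sapply(levs, function(b) {
    m <- mean(d_hat[, b]); s2 <- var(d_hat[, b]); (m * s2 + m^3) / s2 })

  out <- z
  for (bi in seq_along(levs)) {
    b <- levs[bi]
    idx <- which(batch == b)
    ni <- length(idx)
    for (g in seq_len(G)) {
      gh <- g_hat[g, bi]
      d_old <- d_hat[g, bi]
      g_new <- gh
      for (it in seq_len(max_iter)) {
        # the location posterior depends only on the current scale estimate
        g_new <- (ni * t2[bi] * gh + d_old * g_bar[bi]) / (ni * t2[bi] + d_old)
        sum2 <- sum((z[g, idx] - g_new)^2)
        d_new <- (0.5 * sum2 + b_pr[bi]) / (ni / 2 + a_pr[bi] - 1)
        done <- abs(d_new - d_old) / d_old < conv
        d_old <- d_new
        if (done) break
      }
      out[g, idx] <- (z[g, idx] - g_new) / sqrt(d_old)
    }
  }
  out * sqrt(varp) + grand
}

# small two-tissue compendium for fast tests
small_sim_config <- function(seed = 1, ...) {
  defaults <- list(
    n_genes = 300,
    n_datasets = c(blood = 2, synovium = 2),
    n_cases = c(blood = 60, synovium = 40),
    n_controls = c(blood = 30, synovium = 20),
    planted_up = 10, planted_down = 10,
    n_redundant_blocks = 2, block_size = 5,
    n_y_genes = 10, n_oa = 10, n_polyjia = 10, n_treated_pairs = 5,
    seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# quantile-normalize per study, merge, batch-adjust one tissue
prep_tissue <- function(studies) {
  studies <- lapply(studies, function(s) {
    s$values <- quantile_normalize(s$values)
    s
  })
  combat_adjust(merge_studies(studies))$values
}
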