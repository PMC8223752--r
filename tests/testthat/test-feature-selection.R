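test_that("stratified split preserves class proportions and is seeded", {
  labels <- rep(c("case", "control"), c(80, 20))
  sp <- stratified_split(labels, 0.8, seed = 1)
  expect_equal(sum(labels[sp$train] == "case"), 64)
  expect_equal(sum(labels[sp$train] == "control"), 16)
  expect_equal(sum(labels[sp$test] == "case"), 16)
  expect_equal(sum(labels[sp$test] == "control"), 4)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_identical(sp, stratified_split(labels, 0.8, seed = 1))
  expect_false(identical(sp, stratified_split(labels, 0.8, seed = 2)))
  # per-class train fraction within 1/n_c of the target for odd sizes
  labels2 <- rep(c("a", "b"), c(13, 7))
  sp2 <- stratified_split(labels2, 0.8, seed = 3)
  for (cl in c("a", "b")) {
    n_c <- sum(labels2 == cl)
    frac <- sum(labels2[sp2$train] == cl) / n_c
    expect_lte(abs(frac - 0.8), 1 / n_c)
  }
  expect_error(stratified_split(c("a", "b", "b"), 0.8), "< 2 samples")
})

test_that("status-correlation filter keeps |r| >= threshold and drops constants", {
  set.seed(7)
  n <- 200
  status <- rep(c(1, 0), each = n / 2)
  x <- rbind(
    perfect = status * 2 - 1,                       # r = 1
    strong = status + rnorm(n, sd = 0.5),
    weak = status * 0.05 + rnorm(n),                # |r| ~ 0.02
    flat = rep(3, n))
  colnames(x) <- sprintf("s%d", 1:n)
  expect_warning(kept <- correlation_filter(x, status, r_min = 0.25), "constant")
  expect_true(all(c("perfect", "strong") %in% kept))
  expect_false("weak" %in% kept)
  expect_false("flat" %in% kept)
  # point-biserial equivalence with the t statistic
  g <- x["strong", ]
  tt <- stats::t.test(g[status == 1], g[status == 0], var.equal = TRUE)$statistic
  r_from_t <- tt / sqrt(tt^2 + n - 2)
  expect_equal(abs(as.numeric(stats::cor(g, status))), abs(as.numeric(r_from_t)),
               tolerance = 1e-10)
  # a gene just under the threshold is removed
  r_of <- function(v) abs(stats::cor(v, status))
  set.seed(8)
  repeat {
    gb <- status * 0.12 + rnorm(n, sd = 0.25)
    if (r_of(gb) < 0.25 && r_of(gb) > 0.2) break
  }
  x2 <- rbind(border = gb); colnames(x2) <- colnames(x)
  expect_length(correlation_filter(x2, status, r_min = 0.25), 0)
})

test_that("redundancy pruning keeps one representative per correlated block", {
  set.seed(9)
  n <- 100
  latent <- rnorm(n)
  block <- t(sapply(1:5, function(i) latent + rnorm(n, sd = 0.15)))  # r ~ 0.95
  indep <- matrix(rnorm(3 * n), 3)
  x <- rbind(block, indep)
  rownames(x) <- c(sprintf("blk%d", 1:5), sprintf("ind%d", 1:3))
  colnames(x) <- sprintf("s%d", 1:n)
  kept <- redundancy_prune(x, rownames(x), r_max = 0.8,
                           priority = c(5, 1, 2, 3, 4, 6, 7, 8))
  expect_equal(sum(startsWith(kept, "blk")), 1)
  expect_equal(kept[1], "blk2")                      # best-priority block member
  expect_true(all(sprintf("ind%d", 1:3) %in% kept))
  # all pairwise |r| <= r_max: nothing removed
  kept2 <- redundancy_prune(x[6:8, ], rownames(x)[6:8], r_max = 0.8)
  expect_setequal(kept2, sprintf("ind%d", 1:3))
  # two genes r = 0.9: lower priority survives
  expect_equal(redundancy_prune(x, c("blk1", "blk2"), 0.8, priority = c(1, 2)),
               "blk1")
})

test_that("AUROC equals exhaustive pair counting, including ties", {
  expect_equal(auroc(c(1, 2, 3, 2.5, 4, 5), c(1, 1, 1, 0, 0, 0)), 1 / 9)
  expect_equal(auroc(c(2.5, 4, 5, 1, 2, 3), c(1, 1, 1, 0, 0, 0)), 8 / 9)
  expect_equal(auroc(rep(1, 10), rep(c(1, 0), 5)), 0.5)
  expect_equal(auroc(1:10, c(rep(0, 5), rep(1, 5))), 1)
  expect_equal(auroc(1:10, c(rep(1, 5), rep(0, 5))), 0)
  set.seed(10)
  for (i in 1:200) {
    y <- sample(c(rep(1, 8), rep(0, 12)))
    s <- sample(1:8, 20, replace = TRUE)              # many ties
    expect_equal(auroc(s, y), oracle_auroc(s, y), tolerance = 1e-12)
  }
})

test_that("AUCPR: closed forms and monotone-ranking behavior", {
  # all scores tied -> prevalence
  expect_equal(aucpr(rep(2, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  # perfect ranking -> 1
  expect_equal(aucpr(10:1, c(rep(1, 4), rep(0, 6))), 1)
  # hand-computed 4-point case: scores 4>3>2>1, labels 1,0,1,0
  # thresholds: P=1 R=1/2; P=1/2 R=1/2; P=2/3 R=1; P=1/2 R=1
  # AP = 1/2 * 1 + 1/2 * 2/3
  expect_equal(aucpr(c(4, 3, 2, 1), c(1, 0, 1, 0)), 0.5 + 0.5 * 2 / 3)
  expect_error(aucpr(1:3, c(1, 1, 1)), "both classes")
})

test_that("per-gene logistic AUC handles separation and null genes", {
  set.seed(11)
  n <- 60
  y <- rep(c("case", "control"), each = n / 2)
  x_sep <- rbind(g = c(rnorm(n / 2, 10), rnorm(n / 2, 0)))
  colnames(x_sep) <- sprintf("s%d", 1:n)
  sp <- stratified_split(y, 0.8, seed = 1)
  expect_equal(per_gene_auc(x_sep[, sp$train, drop = FALSE], y[sp$train],
                            x_sep[, sp$test, drop = FALSE], y[sp$test], "g"), 1)
  aucs <- vapply(1:30, function(i) {
    set.seed(100 + i)
    xn <- rbind(g = rnorm(200))
    colnames(xn) <- sprintf("s%d", 1:200)
    yy <- rep(c("case", "control"), 100)
    sp <- stratified_split(yy, 0.8, seed = i)
    per_gene_auc(xn[, sp$train, drop = FALSE], yy[sp$train],
                 xn[, sp$test, drop = FALSE], yy[sp$test], "g")
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
  expect_error(per_gene_auc(x_sep, y, x_sep[, 1:3, drop = FALSE],
                            rep("case", 3), "g"), "single class")
})

test_that("no-signal compendium yields an empty final set", {
  empty <- vapply(1:5, function(s) {
    cfg <- small_sim_config(seed = 3000 + s, planted_up = 0, planted_down = 0,
                            n_oa = 0, n_polyjia = 0, n_treated_pairs = 0)
    sim <- generate_compendium(cfg)
    fs <- run_feature_selection(prep_tissue(sim$studies$synovium),
                                prep_tissue(sim$studies$blood),
                                fs_config(n_iterations = 5, base_seed = s))
    length(fs$final_genes) == 0
  }, TRUE)
  expect_gte(mean(empty), 0.8)
})

test_that("feature selection is reproducible and respects co-directionality", {
  cfg <- small_sim_config(seed = 37)
  sim <- generate_compendium(cfg)
  syn <- prep_tissue(sim$studies$synovium)
  blood <- prep_tissue(sim$studies$blood)
  fscfg <- fs_config(n_iterations = 5, base_seed = 7)
  fs1 <- run_feature_selection(syn, blood, fscfg)
  fs2 <- run_feature_selection(syn, blood, fscfg)
  expect_identical(fs1$final_genes, fs2$final_genes)
  expect_identical(fs1$summary, fs2$summary)
  # final set is a subset of every iteration's concordant set
  for (it in fs1$iterations) {
    expect_true(all(fs1$always_selected %in% it$concordant))
    expect_length(it$discordant, 0)
  }
  # raising the AUC threshold never grows the set
  n_at <- vapply(c(0.55, 2 / 3, 0.75, 0.85), function(th) {
    cfg2 <- fscfg; cfg2$auc_threshold <- th
    length(run_feature_selection(syn, blood, cfg2)$final_genes)
  }, 0)
  expect_true(all(diff(n_at) <= 0))
})

test_that("genes with signal in only one tissue never reach the final set", {
  set.seed(41)
  n_genes <- 150; gid <- sprintf("g%03d", seq_len(n_genes))
  mk <- function(n_case, n_ctl, signal_rows) {
    n <- n_case + n_ctl
    x <- matrix(rnorm(n_genes * n, 7, 0.7), n_genes,
                dimnames = list(gid, sprintf("s%s%03d", n_case, seq_len(n))))
    status <- rep(c("case", "control"), c(n_case, n_ctl))
    x[signal_rows, status == "case"] <- x[signal_rows, status == "case"] + 1.2
    compendium(x, data.frame(sample_id = colnames(x), dataset = "d1",
                             status = status))
  }
  both <- 1:10          # shared signal
  solo_a <- 11:20       # tissue A only
  a <- mk(60, 30, c(both, solo_a))
  b <- mk(60, 30, both)
  fs <- run_feature_selection(a, b, fs_config(n_iterations = 4, base_seed = 2))
  expect_length(intersect(fs$final_genes, gid[solo_a]), 0)
  expect_gt(length(intersect(fs$final_genes, gid[both])), 0)
})
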