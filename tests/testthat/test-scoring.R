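panel_of <- function(up, down) list(up_genes = up, down_genes = down)

test_that("score matches the closed form and its invariances", {
  x <- matrix(c(3, 5, 1, 3), 4, 2,
              dimnames = list(c("u1", "u2", "d1", "d2"), c("sA", "sB")))
  x[, 2] <- c(4, 4, 2, 2)
  p <- panel_of(c("u1", "u2"), c("d1", "d2"))
  sc <- ra_score(x, p)
  expect_equal(unname(sc["sA"]), 2^4 - 2^2)         # up GM 2^4, down GM 2^2
  expect_equal(unname(sc["sB"]), 2^4 - 2^2)
  # up list = down list -> 0
  expect_equal(unname(ra_score(x, panel_of(c("u1", "d1"), c("u1", "d1")))),
               c(0, 0))
  # adding c to every panel gene multiplies both GM terms by 2^c
  expect_equal(ra_score(x + 1, p), 2 * sc, tolerance = 1e-12)
  # monotonicity: raising an up gene raises the score; a down gene lowers it
  x_up <- x; x_up["u1", "sA"] <- x_up["u1", "sA"] + 0.5
  expect_gt(ra_score(x_up, p)["sA"], sc["sA"])
  x_dn <- x; x_dn["d1", "sA"] <- x_dn["d1", "sA"] + 0.5
  expect_lt(ra_score(x_dn, p)["sA"], sc["sA"])
  # missing panel genes are dropped with a warning; empty side errors
  expect_warning(ra_score(x, panel_of(c("u1", "zz"), "d1")), "absent")
  expect_error(suppressWarnings(ra_score(x, panel_of("zz", "d1"))),
               "at least one")
})

test_that("group effect recovers a constructed ratio and detects treatment", {
  set.seed(12)
  s1 <- rnorm(500, 10, 1); s2 <- rnorm(500, 5, 1)
  eff <- score_group_effect(c(s1, s2), rep(c("case", "control"), each = 500))
  expect_lt(abs(eff$ratio - 2), 0.02 * 2)
  expect_lt(eff$p, 1e-10)
  same <- score_group_effect(c(s1, s1), rep(c("a", "b"), each = 500))
  expect_equal(same$ratio, 1)
  expect_gt(same$p, 0.99)
  # paired pre/post on the synthetic compendium
  cfg <- small_sim_config(seed = 43, n_treated_pairs = 20, treatment_effect = 0.6)
  sim <- generate_compendium(cfg)
  s <- sim$studies$blood[[1]]
  p <- panel_of(sim$truth$planted_up, sim$truth$planted_down)
  sc <- ra_score(s$values, p)
  ann <- s$annotations
  paired <- ann$pair_id != ""
  eff_t <- suppressWarnings(
    score_group_effect(sc[paired], ann$timepoint[paired],
                       paired = ann$pair_id[paired]))
  expect_lt(eff_t$p, 0.05)
  expect_lt(eff_t$means[["post"]], eff_t$means[["pre"]])
  # non-positive denominator -> NA ratio with warning, p still present
  expect_warning(bad <- score_group_effect(c(rnorm(50, 1), rnorm(50, -1)),
                                           rep(c("x", "y"), each = 50)),
                 "denominator")
  expect_true(is.na(bad$ratio))
  expect_true(is.finite(bad$p))
})

test_that("DAS28 correlation: exact, null, and recovery behavior", {
  set.seed(13)
  sc <- rnorm(60)
  expect_equal(score_das28_correlation(sc, 2 + 3 * sc, rep("d1", 60),
                                       n_boot = 50)$pooled_r, 1,
               tolerance = 1e-12)
  # independence: |r| small at n = 100
  small_r <- vapply(1:20, function(s) {
    set.seed(200 + s)
    abs(score_das28_correlation(rnorm(100), rnorm(100), rep("d", 100),
                                n_boot = 10)$pooled_r)
  }, 0)
  expect_gte(mean(small_r < 0.2), 0.95)
  # pooled estimate recovers a generated r = 0.4 over datasets and seeds
  est <- vapply(1:20, function(s) {
    set.seed(300 + s)
    r_true <- 0.4
    sc <- rnorm(300)
    das <- r_true * sc + sqrt(1 - r_true^2) * rnorm(300)
    ds <- rep(c("d1", "d2", "d3"), each = 100)
    score_das28_correlation(sc, das, ds, n_boot = 10)$pooled_r
  }, 0)
  expect_lt(abs(mean(est) - 0.4), 0.1)
  # constant DAS28 in one dataset is skipped with a warning
  expect_warning(
    res <- score_das28_correlation(rnorm(40), c(2 + 3 * rnorm(20), rep(3, 20)),
                                   rep(c("ok", "flat"), each = 20), n_boot = 10),
    "constant")
  expect_equal(res$per_dataset$dataset, "ok")
})

test_that("Fisher combination matches the chi-square closed form", {
  expect_equal(fisher_combine(0.37), 0.37, tolerance = 1e-12)
  expect_equal(fisher_combine(c(1, 1, 1)), 1)
  expect_equal(fisher_combine(c(0.1, 0.1)),
               stats::pchisq(-2 * (log(0.1) + log(0.1)), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  x2 <- -2 * (log(0.1) + log(0.1))               # 9.2103
  expect_equal(fisher_combine(c(0.1, 0.1)), (1 + x2 / 2) * exp(-x2 / 2),
               tolerance = 1e-12)
  expect_error(fisher_combine(c(0.5, 0)), "floor")
})

test_that("bootstrap OR: direction, null calibration, and analytic agreement", {
  set.seed(14)
  n <- 200
  y <- rep(c("case", "control"), each = n / 2)
  flip <- runif(n) < 0.1
  sc <- ifelse((y == "case") != flip, 1, -1) + rnorm(n, sd = 0.1)
  res <- bootstrap_or(sc, y, c("case", "control"), n_boot = 200, seed = 1)
  z <- (sc - mean(sc)) / sd(sc)
  ref <- exp(stats::coef(stats::glm((y == "case") ~ z, family = binomial()))[2])
  expect_lt(abs(log(res$or) - log(ref)), 0.3)       # within bootstrap noise
  expect_gt(res$or, 1)                               # cases score higher
  expect_gt(res$ci[1], 1)                            # CI excludes 1
  # reversing the contrast inverts the OR
  rev <- bootstrap_or(sc, y, c("control", "case"), n_boot = 200, seed = 1)
  expect_lt(abs(log(rev$or) + log(res$or)), 1e-9)
  # null: CI covers 1 in roughly 95% of runs
  cover <- vapply(1:20, function(s) {
    set.seed(400 + s)
    scn <- rnorm(100)
    r <- bootstrap_or(scn, rep(c("case", "control"), 50), c("case", "control"),
                      n_boot = 100, seed = s)
    r$ci[1] <= 1 && r$ci[2] >= 1
  }, TRUE)
  expect_gte(mean(cover), 0.8)
  expect_error(bootstrap_or(rnorm(6), rep(c("a", "b"), c(3, 3)), c("a", "b")),
               ">= 5")
})

test_that("random-panel null sits below the true planted panel", {
  cfg <- small_sim_config(seed = 47, das28_datasets = c(blood = 2, synovium = 0),
                          das28_noise_sd = 0.3)
  sim <- generate_compendium(cfg)
  m <- merge_studies(sim$studies$blood)
  clin <- generate_clinical_annotations(sim$truth, cfg)
  das <- clin$das28[match(colnames(m$values), clin$sample_id)]
  panel <- panel_of(sim$truth$planted_up, sim$truth$planted_down)
  res <- random_panel_null(m$values, panel, das, n_iter = 50, seed = 5)
  expect_gt(res$true_r, res$null_mean)
  expect_lt(res$p, 0.01)
  # determinism
  res2 <- random_panel_null(m$values, panel, das, n_iter = 50, seed = 5)
  expect_identical(res$null_r, res2$null_r)
})

test_that("per-gene validation finds planted genes and respects availability", {
  cfg <- small_sim_config(seed = 51)
  sim <- generate_compendium(cfg)
  disc <- merge_studies(sim$studies$blood)
  disc <- subset_compendium(disc, samples = disc$annotations$status %in%
                              c("case", "control"))
  disc$values <- zscale_genes(disc$values)
  vsets <- lapply(1:3, function(i) {
    v <- generate_compendium(cfg, truth = sim$truth, seed = 900 + i,
                             dataset_prefix = sprintf("v%d_", i))
    m <- merge_studies(v$studies$blood)
    m <- subset_compendium(m, samples = m$annotations$status %in%
                             c("case", "control"))
    m$values <- zscale_genes(m$values)
    m
  })
  cands <- c(sim$truth$planted_up[1:5], sim$truth$planted_down[1:5])
  pan <- validate_genes(disc, vsets, cands, auc_min = 0.6)
  expect_true(all(pan$up_genes %in% sim$truth$planted_up))
  expect_true(all(pan$down_genes %in% sim$truth$planted_down))
  expect_gt(length(c(pan$up_genes, pan$down_genes)), 0)
  # a candidate absent from one set is dropped with a warning
  v2 <- vsets
  v2[[1]] <- subset_compendium(v2[[1]],
                               genes = setdiff(rownames(v2[[1]]$values), cands[1]))
  expect_warning(pan2 <- validate_genes(disc, v2, cands, auc_min = 0.6),
                 "absent")
  expect_false(cands[1] %in% pan2$table$gene_id)
  # an impossible threshold empties the panel
  pan3 <- validate_genes(disc, vsets, cands, auc_min = 0.999)
  expect_length(c(pan3$up_genes, pan3$down_genes), 0)
})

test_that("planted gene sets outperform random sets across fixed classifiers", {
  wins <- vapply(1:5, function(s) {
    cfg <- small_sim_config(seed = 600 + s)
    sim <- generate_compendium(cfg)
    disc <- merge_studies(sim$studies$blood)
    disc <- subset_compendium(disc, samples = disc$annotations$status %in%
                                c("case", "control"))
    disc$values <- zscale_genes(disc$values)
    vsets <- lapply(1:2, function(i) {
      v <- generate_compendium(cfg, truth = sim$truth, seed = 7000 + 10 * s + i,
                                dataset_prefix = sprintf("w%d_", i))
      m <- merge_studies(v$studies$blood)
      m <- subset_compendium(m, samples = m$annotations$status %in%
                               c("case", "control"))
      m$values <- zscale_genes(m$values)
      m
    })
    planted <- c(sim$truth$planted_up, sim$truth$planted_down)
    nulls <- sim$truth$genes$gene_id[sim$truth$genes$role == "null"]
    set.seed(s)
    rnd <- sample(nulls, length(planted))
    tab <- compare_gene_sets(disc, vsets,
                             list(planted = planted, random = rnd),
                             models = "logistic", seed = s)
    tab$mean_auc[tab$gene_set == "planted"] >
      tab$mean_auc[tab$gene_set == "random"]
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})

test_that("gene-set comparison guards leakage and deduplicates", {
  cfg <- small_sim_config(seed = 61)
  sim <- generate_compendium(cfg)
  disc <- merge_studies(sim$studies$blood)
  disc <- subset_compendium(disc, samples = disc$annotations$status %in%
                              c("case", "control"))
  expect_error(compare_gene_sets(disc, list(disc),
                                 list(s = sim$truth$planted_up),
                                 models = "logistic"),
               "leakage")
  v <- generate_compendium(cfg, truth = sim$truth, seed = 999,
                           dataset_prefix = "vx_")
  vm <- merge_studies(v$studies$blood)
  vm <- subset_compendium(vm, samples = vm$annotations$status %in%
                            c("case", "control"))
  expect_warning(compare_gene_sets(disc, list(vm),
                                   list(s = rep(sim$truth$planted_up[1:4], 2)),
                                   models = "logistic"),
                 "duplicates")
})
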