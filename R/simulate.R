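#' Simulation configuration for the synthetic two-tissue compendium
#'
#' Defines the study conditions the generator emulates: several datasets per
#' tissue on a log2 microarray-like scale, a planted co-directional disease
#' signal shared by synovium and blood (stronger in synovium), blocks of
#' highly inter-correlated genes, per-dataset location/scale batch effects,
#' Y-chromosome-driven sex signal, treatment attenuation of the disease
#' signal, a latent disease-burden variable driving a DAS28-like disease
#' activity measure, and the blood case/control imbalance typical of public
#' compendia (here 300:90 across four datasets, mirroring the roughly 3.5:1
#' imbalance of real whole-blood collections; synovium 90:30 across three).
#'
#' @param n_genes total number of genes.
#' @param n_datasets named counts of datasets per tissue.
#' @param n_cases,n_controls named per-tissue totals, split as evenly as
#'   possible across that tissue's datasets.
#' @param planted_up,planted_down counts of co-directionally planted
#'   disease genes (same direction in both tissues by construction).
#' @param lfc_range range of absolute blood log2 fold-changes for planted
#'   genes; each gene's magnitude is drawn uniformly from this range.
#' @param tissue_multiplier named per-tissue multiplier applied to the drawn
#'   blood-scale magnitude (synovium > blood).
#' @param n_redundant_blocks,block_size,block_corr number and size of
#'   correlated gene blocks and their within-block Pearson correlation
#'   (blocks are disjoint from planted genes and carry no disease signal).
#' @param batch_shift_sd sd of the additive per-gene, per-dataset shift.
#' @param batch_scale_sd sd (log scale) of the multiplicative per-gene,
#'   per-dataset residual-scale factor.
#' @param n_y_genes,sex_effect,prop_male,missing_sex_frac count of
#'   male-specific (Y-chromosome-like) genes, their log2 elevation in males,
#'   the male fraction, and the fraction of samples emitted with a blank sex
#'   annotation.
#' @param treated_fraction fraction of cases receiving treatment.
#' @param treatment_effect fraction of the planted log2 signal removed in
#'   treated cases (0 = no effect, 1 = signal fully suppressed).
#' @param n_treated_pairs number of pre/post-treatment sample pairs added to
#'   the first blood dataset (pre = untreated state, post = attenuated).
#' @param das28_intercept,das28_slope,das28_noise_sd linear map from the
#'   latent per-case disease burden to the simulated DAS28 value.
#' @param das28_datasets named counts of datasets per tissue that carry
#'   DAS28 annotations (cases only).
#' @param n_oa,oa_overlap_fraction,oa_magnitude osteoarthritis-like samples
#'   added to the first synovium dataset: they express the configured
#'   fraction of the planted genes at `oa_magnitude` times the RA effect.
#' @param n_polyjia,polyjia_magnitude polyJIA-like samples added to the
#'   second blood dataset, expressing the full blood signal at the given
#'   relative magnitude.
#' @param baseline_mean,baseline_sd per-gene baseline log2 expression
#'   distribution.
#' @param var_prior_df,var_prior_scale parameters of the scaled
#'   inverse-chi-square distribution the per-gene residual variances are
#'   drawn from (chosen so empirical-Bayes variance moderation has
#'   something to shrink).
#' @param var_floor additive variance floor common to all genes,
#'   emulating the technical noise floor of array data and keeping
#'   per-gene standardized effects in a realistic range.
#' @param burden_mean,burden_sd latent disease-burden distribution for
#'   affected samples (controls have burden 0).
#' @param rf_positive_frac fraction of cases labelled rheumatoid-factor
#'   positive, assigned independently of the planted signal.
#' @param seed integer; fully determines the generated compendium.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       n_datasets = c(blood = 4, synovium = 3),
                       n_cases = c(blood = 300, synovium = 90),
                       n_controls = c(blood = 90, synovium = 30),
                       planted_up = 30, planted_down = 30,
                       lfc_range = c(0.6, 1.0),
                       tissue_multiplier = c(blood = 1, synovium = 1.7),
                       n_redundant_blocks = 5, block_size = 8,
                       block_corr = 0.9,
                       batch_shift_sd = 0.4, batch_scale_sd = 0.15,
                       n_y_genes = 20, sex_effect = 3, prop_male = 0.5,
                       missing_sex_frac = 0.4,
                       treated_fraction = 0.3, treatment_effect = 0.5,
                       n_treated_pairs = 25,
                       das28_intercept = 2, das28_slope = 2.5,
                       das28_noise_sd = 0.5,
                       das28_datasets = c(blood = 2, synovium = 1),
                       n_oa = 30, oa_overlap_fraction = 0.5,
                       oa_magnitude = 0.5,
                       n_polyjia = 40, polyjia_magnitude = 0.8,
                       baseline_mean = 7, baseline_sd = 1.5,
                       var_prior_df = 6, var_prior_scale = 0.2,
                       var_floor = 0.15,
                       burden_mean = 1, burden_sd = 0.15,
                       rf_positive_frac = 0.7,
                       seed = 1) {
  cfg <- as.list(environment())
  tissues <- names(cfg$n_datasets)
  if (is.null(tissues) || !setequal(tissues, names(cfg$n_cases)) ||
      !setequal(tissues, names(cfg$n_controls)) ||
      !setequal(tissues, names(cfg$tissue_multiplier)))
    stopf("n_datasets, n_cases, n_controls and tissue_multiplier must share tissue names")
  counts <- c(cfg$n_genes, cfg$planted_up, cfg$planted_down,
              cfg$n_redundant_blocks, cfg$block_size, cfg$n_y_genes,
              cfg$n_datasets, cfg$n_cases, cfg$n_controls)
  if (any(counts < 0)) stopf("all counts must be >= 0")
  used <- cfg$planted_up + cfg$planted_down +
    cfg$n_redundant_blocks * cfg$block_size + cfg$n_y_genes
  if (used > cfg$n_genes)
    stopf("planted + block + Y genes (%d) exceed n_genes (%d)", used, cfg$n_genes)
  if (cfg$lfc_range[1] <= 0 || diff(cfg$lfc_range) < 0)
    stopf("lfc_range must have a positive lower bound and be non-decreasing")
  if (cfg$block_corr < 0 || cfg$block_corr >= 1)
    stopf("block_corr must be in [0, 1)")
  if (cfg$treatment_effect < 0 || cfg$treatment_effect > 1)
    stopf("treatment_effect must be in [0, 1]")
  if (any(cfg$das28_datasets > cfg$n_datasets[names(cfg$das28_datasets)]))
    stopf("das28_datasets cannot exceed n_datasets")
  structure(cfg, class = "sim_config")
}

# split a total across k datasets as evenly as possible
split_even <- function(total, k) {
  base <- rep(total %/% k, k)
  extra <- total %% k
  if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1
  base
}

# gene-level truth: identities, roles, effect sizes, residual sds
draw_gene_truth <- function(cfg) {
  ng <- cfg$n_genes
  ids <- sprintf("G%05d", seq_len(ng))
  role <- rep("null", ng)
  up <- seq_len(cfg$planted_up)
  down <- cfg$planted_up + seq_len(cfg$planted_down)
  nblockg <- cfg$n_redundant_blocks * cfg$block_size
  blockg <- cfg$planted_up + cfg$planted_down + seq_len(nblockg)
  yg <- cfg$planted_up + cfg$planted_down + nblockg + seq_len(cfg$n_y_genes)
  role[up] <- "up"; role[down] <- "down"
  role[blockg] <- "block"; role[yg] <- "y"
  block_id <- rep(NA_integer_, ng)
  if (nblockg > 0)
    block_id[blockg] <- rep(seq_len(cfg$n_redundant_blocks),
                            each = cfg$block_size)

  mu <- rnorm(ng, cfg$baseline_mean, cfg$baseline_sd)
  # residual sd^2 ~ floor + scaled inverse-chi-square(d0, s0^2)
  s2 <- cfg$var_floor + cfg$var_prior_df * cfg$var_prior_scale /
    rchisq(ng, df = cfg$var_prior_df)
  mag <- runif(ng, cfg$lfc_range[1], cfg$lfc_range[2])
  sign <- ifelse(role == "up", 1, ifelse(role == "down", -1, 0))
  lfc <- sapply(names(cfg$n_datasets), function(t)
    sign * mag * cfg$tissue_multiplier[[t]])
  colnames(lfc) <- names(cfg$n_datasets)

  n_oa_genes <- round(cfg$oa_overlap_fraction * (cfg$planted_up + cfg$planted_down))
  oa_genes <- if (n_oa_genes > 0)
    sort(sample(c(up, down), n_oa_genes)) else integer(0)

  list(gene_id = ids, role = role, block = block_id, mu = mu, sd = sqrt(s2),
       lfc = lfc, oa_gene = seq_len(ng) %in% oa_genes,
       planted_up = ids[up], planted_down = ids[down], y_genes = ids[yg])
}

# simulate one dataset's matrix + sample table from gene-level truth;
# all columns (including post-treatment partners) are drawn in one pass
# so batch, block and sex structure is shared by every sample
simulate_dataset <- function(gt, cfg, tissue, ds_name, n_case, n_control,
                             das28_annotated, extra_status = character(0),
                             n_pairs = 0) {
  ng <- length(gt$gene_id)
  status <- c(rep("case", n_case), rep("control", n_control), extra_status)
  n_main <- length(status)
  n_pairs <- min(n_pairs, n_case)
  pair_of <- seq_len(n_pairs)                  # case indices with a post sample
  if (n_pairs > 0) status <- c(status, rep("case", n_pairs))
  n <- length(status)
  is_post <- c(rep(FALSE, n_main), rep(TRUE, n_pairs))

  sid <- character(n)
  sid[!is_post] <- sprintf("%s_S%03d", ds_name, seq_len(n_main))
  if (n_pairs > 0) sid[is_post] <- sprintf("%s_P%03d", ds_name, pair_of)

  sex <- ifelse(runif(n_main) < cfg$prop_male, "male", "female")
  treated <- status[seq_len(n_main)] == "case" & runif(n_main) < cfg$treated_fraction
  burden_main <- ifelse(status[seq_len(n_main)] == "control", 0,
                        pmax(0.2, rnorm(n_main, cfg$burden_mean, cfg$burden_sd)))
  if (n_pairs > 0) treated[pair_of] <- TRUE
  # post samples share subject-level sex and burden with their pre partner
  sex <- c(sex, sex[pair_of])
  burden <- c(burden_main, burden_main[pair_of])
  treated <- c(treated, rep(TRUE, n_pairs))
  treatment <- ifelse(treated, "dmard", "")

  pair_id <- rep("", n); timepoint <- rep("", n)
  if (n_pairs > 0) {
    pr <- sprintf("%s_pair%02d", ds_name, pair_of)
    timepoint[pair_of] <- "pre"; pair_id[pair_of] <- pr
    timepoint[is_post] <- "post"; pair_id[is_post] <- pr
  }

  # planted-signal multiplier: treated cases attenuated, except pre-treatment
  # samples which carry the full signal by construction
  att <- ifelse(treated, 1 - cfg$treatment_effect, 1)
  att[timepoint == "pre"] <- 1
  sig_mult <- numeric(n)
  sig_mult[status == "case"] <- (burden * att)[status == "case"]
  sig_mult[status == "OA"] <- burden[status == "OA"] * cfg$oa_magnitude
  sig_mult[status == "polyJIA"] <- burden[status == "polyJIA"] * cfg$polyjia_magnitude

  # per-dataset batch effects: additive shift + multiplicative residual scale
  shift <- rnorm(ng, 0, cfg$batch_shift_sd)
  scale <- exp(rnorm(ng, 0, cfg$batch_scale_sd))
  lfc_t <- gt$lfc[, tissue]

  x <- matrix(rnorm(ng * n), ng, n) * (scale * gt$sd) + gt$mu + shift
  eff <- outer(lfc_t, sig_mult)
  if (any(status == "OA"))                     # OA expresses only the shared subset
    eff[!gt$oa_gene, status == "OA"] <- 0
  x <- x + eff

  # correlated blocks from a shared per-sample latent factor
  if (cfg$n_redundant_blocks > 0 && cfg$block_size > 0) {
    for (b in seq_len(cfg$n_redundant_blocks)) {
      rows <- which(!is.na(gt$block) & gt$block == b)
      f <- rnorm(n)
      noise <- matrix(rnorm(length(rows) * n), length(rows), n)
      z <- sqrt(cfg$block_corr) * matrix(f, length(rows), n, byrow = TRUE) +
        sqrt(1 - cfg$block_corr) * noise
      x[rows, ] <- gt$mu[rows] + shift[rows] +
        z * (scale[rows] * gt$sd[rows])
    }
  }

  yrows <- which(gt$role == "y")
  if (length(yrows))
    x[yrows, sex == "male"] <- x[yrows, sex == "male"] + cfg$sex_effect
  rownames(x) <- gt$gene_id
  colnames(x) <- sid

  das28 <- rep(NA_real_, n)
  if (das28_annotated) {
    aff <- status != "control"
    das28[aff] <- cfg$das28_intercept + cfg$das28_slope * burden[aff] +
      rnorm(sum(aff), 0, cfg$das28_noise_sd)
  }
  samples <- data.frame(
    sample_id = sid, dataset = ds_name, tissue = tissue, status = status,
    sex = sex, treatment = treatment, das28 = das28,
    rf_status = "", pair_id = pair_id, timepoint = timepoint,
    burden = burden, das28_annotated = das28_annotated,
    stringsAsFactors = FALSE)
  list(values = x, samples = samples)
}

#' Generate a synthetic two-tissue expression compendium with ground truth
#'
#' Draws per-gene baselines, residual variances and planted co-directional
#' effect sizes once, then simulates the configured number of datasets per
#' tissue, each with its own additive/multiplicative batch effect.  Disease
#' samples carry the planted signal scaled by a latent per-sample burden;
#' correlated blocks come from a shared latent factor; Y-genes are elevated
#' in males; OA/polyJIA-like samples express partial or tissue-restricted
#' versions of the signal.  The ground-truth record allows every downstream
#' stage to be scored against the generating model.
#'
#' @param config a [sim_config()].
#' @param truth optional gene-level truth from a previous call; when given,
#'   gene identities, baselines and effect sizes are reused and only new
#'   samples/batches are drawn — this is how independent validation cohorts
#'   from the same population are produced.
#' @param seed optional seed overriding `config$seed` (used for validation
#'   cohorts drawn from the same gene-level truth).
#' @param dataset_prefix string prepended to dataset (and hence sample)
#'   identifiers; give validation cohorts a distinct prefix so their
#'   sample ids can never collide with the discovery compendium.
#' @return a list with `studies` (named per tissue: list of `compendium`
#'   objects, one per dataset) and `truth` (gene table, sample table, and
#'   planted/Y/block id vectors).
#' @export
generate_compendium <- function(config, truth = NULL, seed = NULL,
                                dataset_prefix = "") {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  with_seed(seed, {
    gt <- if (is.null(truth)) draw_gene_truth(config) else truth$gene_level
    studies <- list()
    sample_tabs <- list()
    for (tissue in names(config$n_datasets)) {
      k <- config$n_datasets[[tissue]]
      cases <- split_even(config$n_cases[[tissue]], k)
      ctrls <- split_even(config$n_controls[[tissue]], k)
      das_k <- if (tissue %in% names(config$das28_datasets))
        config$das28_datasets[[tissue]] else 0
      tissue_studies <- vector("list", k)
      for (d in seq_len(k)) {
        ds_name <- sprintf("%s%s%02d", dataset_prefix, tissue, d)
        extra <- character(0)
        n_pairs <- 0
        if (tissue == "blood" && d == 1) n_pairs <- config$n_treated_pairs
        if (tissue == "blood" && d == 2 && config$n_polyjia > 0)
          extra <- rep("polyJIA", config$n_polyjia)
        if (tissue == "synovium" && d == 1 && config$n_oa > 0)
          extra <- rep("OA", config$n_oa)
        sim <- simulate_dataset(gt, config, tissue, ds_name,
                                cases[d], ctrls[d],
                                das28_annotated = d <= das_k,
                                extra_status = extra, n_pairs = n_pairs)
        ann <- sim$samples[, c("sample_id", "dataset", "tissue", "status",
                               "sex", "treatment", "das28", "rf_status",
                               "pair_id", "timepoint")]
        # emit a fraction of samples with blank sex, mirroring incomplete
        # public annotations; true sex stays in the ground-truth table
        blank <- runif(nrow(ann)) < config$missing_sex_frac
        ann$sex[blank] <- ""
        tissue_studies[[d]] <- compendium(sim$values, ann)
        sample_tabs[[ds_name]] <- sim$samples
      }
      names(tissue_studies) <- sprintf("%s%s%02d", dataset_prefix, tissue,
                                       seq_len(k))
      studies[[tissue]] <- tissue_studies
    }
    gene_tab <- data.frame(
      gene_id = gt$gene_id, role = gt$role, block = gt$block,
      baseline = gt$mu, residual_sd = gt$sd,
      lfc_blood = gt$lfc[, "blood"],
      lfc_synovium = if ("synovium" %in% colnames(gt$lfc))
        gt$lfc[, "synovium"] else NA_real_,
      oa_gene = gt$oa_gene, stringsAsFactors = FALSE)
    truth_out <- list(
      gene_level = gt,
      genes = gene_tab,
      samples = do.call(rbind, c(sample_tabs, list(make.row.names = FALSE))),
      planted_up = gt$planted_up, planted_down = gt$planted_down,
      y_genes = gt$y_genes,
      block_membership = stats::setNames(gt$block, gt$gene_id))
    list(studies = studies, truth = truth_out)
  })
}

#' Derive the clinical annotation table from a generated compendium
#'
#' Emits per-sample clinical fields for downstream association analyses:
#' the simulated DAS28 value for annotated datasets, a rheumatoid-factor
#' status assigned to cases independently of the planted signal (so the
#' composite score is RF-agnostic by construction), and the pre/post
#' treatment pairing of the longitudinal samples.
#'
#' @param truth the `truth` element returned by [generate_compendium()].
#' @param config the [sim_config()] used to generate it.
#' @param seed optional seed for the RF-status assignment (defaults to
#'   `config$seed + 1`).
#' @return data.frame with `sample_id, dataset, tissue, status, das28,
#'   rf_status, pair_id, timepoint`.
#' @export
generate_clinical_annotations <- function(truth, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  s <- truth$samples
  with_seed(seed %||% (config$seed + 1L), {
    rf <- rep("", nrow(s))
    case <- s$status == "case"
    rf[case] <- ifelse(runif(sum(case)) < config$rf_positive_frac,
                       "positive", "negative")
    data.frame(sample_id = s$sample_id, dataset = s$dataset,
               tissue = s$tissue, status = s$status,
               das28 = ifelse(s$das28_annotated, s$das28, NA_real_),
               rf_status = rf, pair_id = s$pair_id,
               timepoint = s$timepoint, stringsAsFactors = FALSE)
  })
}
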