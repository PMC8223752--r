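#' Pipeline configuration
#'
#' Bundles the simulation and feature-selection configurations with the
#' scoring thresholds and the master seed.  The configuration round-trips
#' losslessly through YAML ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param sim a [sim_config()].
#' @param fs an [fs_config()].
#' @param validation_auc_min mean validation AUROC a gene must exceed to
#'   enter the score panel (default 0.8).
#' @param n_validation_sets independent validation cohorts to simulate per
#'   tissue-mixture (default 5: 3 blood, 2 synovium).
#' @param seed master seed; stage seeds are derived from it and logged.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), fs = fs_config(n_iterations = 25),
                            validation_auc_min = 0.8,
                            n_validation_sets = 5, seed = 1) {
  stopifnot(inherits(sim, "sim_config"), inherits(fs, "fs_config"))
  structure(list(sim = sim, fs = fs,
                 validation_auc_min = validation_auc_min,
                 n_validation_sets = n_validation_sets, seed = seed),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- rapply(unclass(config), function(x)
    if (is.null(names(x))) x else as.list(x), how = "replace")
  plain$sim <- lapply(unclass(config$sim), function(x)
    if (!is.null(names(x))) as.list(x) else x)
  plain$fs <- unclass(config$fs)
  yaml::write_yaml(plain, path, precision = 17)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unvec <- function(x) lapply(x, function(v)
    if (is.list(v)) unlist(v) else v)
  sim <- do.call(sim_config, unvec(raw$sim))
  fs <- do.call(fs_config, unvec(raw$fs))
  pipeline_config(sim = sim, fs = fs,
                  validation_auc_min = raw$validation_auc_min,
                  n_validation_sets = raw$n_validation_sets,
                  seed = raw$seed)
}

# per-study quantile normalization, merge, sex imputation, batch adjustment
preprocess_tissue <- function(studies, y_genes) {
  studies <- lapply(studies, function(s) {
    s$values <- quantile_normalize(s$values)
    s$flags$quantile_normalized <- TRUE
    s
  })
  merged <- merge_studies(studies)
  merged$annotations$sex <- impute_sex(merged$values, y_genes,
                                       annotated = merged$annotations$sex)
  adj <- combat_adjust(merged)
  list(raw = merged, adjusted = adj$values, batch_model = adj$model)
}

#' Run the full discovery-to-score pipeline on synthetic data
#'
#' Simulates the two-tissue compendium, preprocesses each tissue
#' (intra-study quantile normalization, merging on common genes, sex
#' imputation, empirical-Bayes batch adjustment), fits covariate-adjusted
#' differential expression per tissue and their cross-tissue overlap, runs
#' the iterative feature selection, validates the selected genes on
#' independently simulated cohorts, computes the composite score and its
#' clinical association battery, and evaluates batch diagnostics before
#' and after adjustment.  Every intermediate table plus a summary JSON is
#' written under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the list of stage results (also serialized under
#'   `out_dir`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) {
    msg <- sprintf(...)
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), msg),
        file = log_path, append = TRUE)
    message(msg)
  }
  seeds <- list(simulate = config$seed, validation = config$seed + 1000L,
                fs = config$fs$base_seed, diagnostics = config$seed + 2000L,
                scoring = config$seed + 3000L)
  logf("stage seeds: %s",
       paste(sprintf("%s=%d", names(seeds), unlist(seeds)), collapse = " "))

  # --- simulate ---------------------------------------------------------
  logf("simulate: generating discovery compendium")
  sim <- generate_compendium(config$sim, seed = seeds$simulate)
  clin <- generate_clinical_annotations(sim$truth, config$sim)
  write_ground_truth(sim$truth, file.path(out_dir, "truth"))
  data.table::fwrite(clin, file.path(out_dir, "clinical_annotations.tsv"),
                     sep = "\t")

  # --- preprocess -------------------------------------------------------
  logf("preprocess: quantile normalization, merge, sex imputation, batch adjustment")
  tissues <- names(sim$studies)
  prep <- lapply(tissues, function(t)
    preprocess_tissue(sim$studies[[t]], sim$truth$y_genes))
  names(prep) <- tissues
  for (t in tissues)
    write_matrix(prep[[t]]$adjusted, file.path(out_dir, paste0(t, "_adjusted.tsv")))

  # --- differential expression -----------------------------------------
  logf("differential expression per tissue")
  de <- lapply(prep, function(p) {
    comp <- subset_compendium(p$adjusted,
                              samples = p$adjusted$annotations$status %in%
                                c("case", "control"))
    ann <- comp$annotations
    covars <- ann[, c("sex", "treatment"), drop = FALSE]
    covars <- covars[, vapply(covars, function(v) length(unique(v)) > 1, TRUE),
                     drop = FALSE]
    moderate_statistics(fit_linear_de(comp$values, ann$status,
                                      if (ncol(covars)) covars else NULL))
  })
  common_n <- length(intersect(rownames(prep[[1]]$adjusted$values),
                               rownames(prep[[2]]$adjusted$values)))
  overlap <- cross_tissue_overlap(de[[1]], de[[2]], background_n = common_n)
  for (t in tissues)
    data.table::fwrite(de[[t]], file.path(out_dir, paste0("de_", t, ".tsv")),
                       sep = "\t")

  # --- feature selection ------------------------------------------------
  logf("feature selection: %d iterations", config$fs$n_iterations)
  fs <- run_feature_selection(prep$synovium$adjusted, prep$blood$adjusted,
                              config$fs)
  if (!is.null(fs$summary))
    data.table::fwrite(fs$summary, file.path(out_dir, "fs_summary.tsv"),
                       sep = "\t")

  # --- validation cohorts and per-gene validation -----------------------
  logf("validation: %d independent cohorts", config$n_validation_sets)
  val_mix <- rep(c("blood", "synovium"), length.out = config$n_validation_sets)
  val_cfg <- config$sim
  val_sets <- lapply(seq_len(config$n_validation_sets), function(i) {
    tissue <- val_mix[i]
    vs <- generate_compendium(val_cfg, truth = sim$truth,
                              seed = seeds$validation + i,
                              dataset_prefix = sprintf("val%d_", i))
    merged <- merge_studies(vs$studies[[tissue]])
    merged <- subset_compendium(merged,
                                samples = merged$annotations$status %in%
                                  c("case", "control"))
    merged$values <- zscale_genes(merged$values)
    merged
  })
  disc_blood <- subset_compendium(prep$blood$adjusted,
                                  samples = prep$blood$adjusted$annotations$status %in%
                                    c("case", "control"))
  disc_blood_z <- disc_blood
  disc_blood_z$values <- zscale_genes(disc_blood$values)
  panel <- if (length(fs$final_genes))
    validate_genes(disc_blood_z, val_sets, fs$final_genes,
                   auc_min = config$validation_auc_min,
                   directions = fs$final_directions)
  else NULL
  if (!is.null(panel))
    data.table::fwrite(panel$table, file.path(out_dir, "panel.tsv"), sep = "\t")

  # --- scoring ----------------------------------------------------------
  scoring <- NULL
  if (!is.null(panel) &&
      length(panel$up_genes) >= 1 && length(panel$down_genes) >= 1) {
    logf("scoring: composite score and clinical associations")
    blood_all <- prep$blood$adjusted
    scores <- ra_score(blood_all, panel)
    ann <- blood_all$annotations
    cc <- ann$status %in% c("case", "control")
    eff <- score_group_effect(scores[cc], ann$status[cc])
    clin_idx <- match(ann$sample_id, clin$sample_id)
    das <- clin$das28[clin_idx]
    das_cor <- score_das28_correlation(scores, das, ann$dataset,
                                       seed = seeds$scoring)
    paired_idx <- ann$pair_id != ""
    trt <- if (any(paired_idx))
      score_group_effect(scores[paired_idx], ann$timepoint[paired_idx],
                         paired = ann$pair_id[paired_idx]) else NULL
    null_cmp <- random_panel_null(blood_all, panel, das,
                                  seed = seeds$scoring + 1L)
    data.table::fwrite(data.frame(sample_id = names(scores),
                                  ra_score = scores),
                       file.path(out_dir, "ra_scores.tsv"), sep = "\t")
    scoring <- list(effect = eff, das28 = das_cor, treatment = trt,
                    random_panel = null_cmp)
  } else logf("scoring skipped: empty panel")

  # --- diagnostics ------------------------------------------------------
  logf("diagnostics: batch predictability and PC association")
  diagnostics <- lapply(tissues, function(t) {
    raw <- prep[[t]]$raw; adj <- prep[[t]]$adjusted
    list(mlogloss_uncorrected = as.numeric(
           batch_predictability(raw, raw$annotations$dataset,
                                seed = seeds$diagnostics)),
         mlogloss_corrected = as.numeric(
           batch_predictability(adj, adj$annotations$dataset,
                                seed = seeds$diagnostics)),
         kw_uncorrected = pc_batch_kruskal(raw),
         kw_corrected = pc_batch_kruskal(adj))
  })
  names(diagnostics) <- tissues

  summary <- list(
    seed = config$seed,
    n_common_genes = common_n,
    de_calls = lapply(de, function(d) {
      cl <- call_de(d); list(up = length(cl$up), down = length(cl$down)) }),
    overlap = list(up = length(overlap$up), down = length(overlap$down),
                   p_up = overlap$p_up, p_down = overlap$p_down),
    feature_selection = list(always = length(fs$always_selected),
                             final = length(fs$final_genes)),
    panel = if (!is.null(panel)) list(up = panel$up_genes,
                                      down = panel$down_genes) else NULL,
    scoring = if (!is.null(scoring)) list(
      case_control_ratio = scoring$effect$ratio,
      case_control_p = scoring$effect$p,
      das28_pooled_r = scoring$das28$pooled_r,
      das28_fisher_p = scoring$das28$fisher_p,
      treatment_p = scoring$treatment$p %||% NA_real_,
      random_panel_p = scoring$random_panel$p) else NULL,
    diagnostics = lapply(diagnostics, function(d) list(
      mlogloss_uncorrected = d$mlogloss_uncorrected,
      mlogloss_corrected = d$mlogloss_corrected,
      kw_median_p_uncorrected = stats::median(d$kw_uncorrected$p),
      kw_median_p_corrected = stats::median(d$kw_corrected$p))))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("done")
  invisible(list(sim = sim, preprocess = prep, de = de, overlap = overlap,
                 fs = fs, panel = panel, scoring = scoring,
                 diagnostics = diagnostics, summary = summary))
}
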