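#' Run the full analysis end-to-end on a synthetic cohort
#'
#' Generates every input from a [sim_config()], then executes the whole
#' pipeline in order: expression prep (log2), paired differential
#' expression with the aggregate FDR estimate, essentiality partition of
#' the metastasis-high genes with overlap statistics, normal-tissue
#' confound diagnostics, cross-study replication of the essential set,
#' signature scoring with Cox / log-rank survival association and the
#' random-signature null, nearest-centroid subtype assignment, TF and
#' knockdown target enrichment, and single-cell scoring. Writes stage
#' outputs under `outdir` and a machine-readable JSON manifest
#' (`manifest.json`) with the seed, thresholds, per-stage headline
#' statistics and file checksums. Two runs with the same config produce
#' byte-identical manifests.
#'
#' @param config a [sim_config()]; its `seed` drives all randomness.
#' @param outdir output directory (created if needed).
#' @param de_alpha per-gene threshold for the paired analysis;
#'   default 0.001.
#' @param effect_threshold essentiality score cutoff; default -0.75.
#' @param min_fraction essential-line fraction bound; default 0.10.
#' @param tissue_alpha normal-tissue contrast threshold; default 1e-6.
#' @param replication_alpha compendium replication threshold;
#'   default 0.05.
#' @param knockdown_threshold under-expression cutoff; default -0.5.
#' @param window TF upstream window (bp); default 2000.
#' @param n_random random signatures in the null; default 100.
#' @return the manifest, invisibly (a list).
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         de_alpha = 0.001, effect_threshold = -0.75,
                         min_fraction = 0.10, tissue_alpha = 1e-6,
                         replication_alpha = 0.05,
                         knockdown_threshold = -0.5, window = 2000,
                         n_random = 100) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  truth <- make_truth(config)
  gen <- stage("simulate", generate_paired_cohort(config, truth))
  cohort <- gen$cohort

  # prep: TPM -> log2
  log2_cohort <- cohort
  log2_cohort$expr <- log2_transform(cohort$expr, 1)

  de <- stage("paired_de", paired_differential(log2_cohort))
  sel <- select_differential(de, de_alpha, "both")
  fdr <- estimate_fdr(nrow(de), de_alpha, length(sel$higher) +
                        length(sel$lower))
  write_expression_tsv(cohort$expr, file.path(outdir, "expression_tpm.tsv"))
  write.table(de, file.path(outdir, "paired_de.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  scores <- stage("essentiality", generate_effect_scores(truth, config))
  counts <- count_essential_lines(scores, effect_threshold)
  part <- suppressMessages(
    classify_genes(sel$higher, counts, min_fraction, effect_threshold))
  essential <- partition_genes(part, "essential")
  nonessential <- partition_genes(part, "nonessential")
  dep_essential <- counts$gene[counts$n_essential / pmax(counts$n_assayed, 1) >
                                 min_fraction]
  ov <- overlap_stats(sel$higher, dep_essential, de$gene)
  write.table(as.data.frame(unclass(part)),
              file.path(outdir, "essentiality_partition.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  panel <- stage("confound", generate_normal_tissue_panel(truth, config))
  contrast <- tissue_contrast(panel$panel, panel$tissue, "breast",
                              tissue_alpha)
  crosstab <- crosstab_sets(sel$higher, sel$lower,
                            contrast$high_in_target,
                            contrast$low_in_target, de$gene)
  site_ess <- site_foldchange_summary(log2_cohort, essential)
  site_non <- site_foldchange_summary(log2_cohort, nonessential)

  comp <- stage("replication", {
    studies <- lapply(generate_compendium(truth, config), center_and_scale)
    replication_test(studies, essential, replication_alpha)
  })

  surv_data <- stage("survival", generate_survival_cohort(truth, config))
  sig_scores <- suppressMessages(score_cohort(surv_data$expr, essential))
  cox <- cox_univariate(sig_scores, surv_data$surv)
  lr <- logrank_groups(sig_scores, surv_data$surv)
  null <- random_signature_null(surv_data$expr, essential, surv_data$surv,
                                n = n_random,
                                seed = .substream(config$seed, "null"))

  sub <- stage("subtype", {
    model <- build_centroids(log2_cohort$expr,
                             cohort$samples$subtype[
                               match(colnames(cohort$expr),
                                     cohort$samples$sample)])
    asg <- assign_subtype(log2_cohort$expr, model,
                          cohort$samples$role[
                            match(colnames(cohort$expr),
                                  cohort$samples$sample)])
    planted <- cohort$samples$subtype[match(asg$sample,
                                            cohort$samples$sample)]
    list(assignments = asg, accuracy = mean(asg$subtype == planted))
  })

  reg <- stage("enrichment", {
    rd <- generate_regulator_data(truth, config)
    tf_sets <- map_tf_targets(rd$sites, rd$loci, window)
    kd_sets <- knockdown_targets(rd$knockdown, knockdown_threshold)
    list(tf = fisher_enrichment(essential, tf_sets, de$gene),
         kd = fisher_enrichment(essential, kd_sets, de$gene))
  })

  sc <- stage("single_cell", {
    scd <- generate_single_cell(truth, config)
    ess_scores <- score_cells(scd$counts, essential)
    list(summary = summarize_by_type(ess_scores, scd$cell_type))
  })

  files <- list.files(outdir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    thresholds = list(de_alpha = de_alpha,
                      effect_threshold = effect_threshold,
                      min_fraction = min_fraction,
                      tissue_alpha = tissue_alpha,
                      replication_alpha = replication_alpha,
                      knockdown_threshold = knockdown_threshold,
                      window = window, n_random = n_random),
    stages = list(
      paired_de = list(n_genes = nrow(de), n_higher = length(sel$higher),
                       n_lower = length(sel$lower), fdr = fdr),
      essentiality = list(n_essential = length(essential),
                          n_nonessential = length(nonessential),
                          overlap = ov$a, expected = ov$expected,
                          chisq_p = ov$chisq_p, fisher_p = ov$fisher_p),
      confound = list(n_breast_high = length(contrast$high_in_target),
                      met_high_x_breast_low_p =
                        crosstab$met_high_x_tissue_low$fisher_p,
                      site_median_var_essential =
                        var(site_ess$by_site$q50),
                      site_median_var_nonessential =
                        var(site_non$by_site$q50)),
      replication = list(fraction = comp$replicated_fraction,
                         fisher_p = comp$overlap$fisher_p),
      survival = list(cox_coef = cox$coef, cox_p = cox$p, logrank_p = lr$p,
                      null_rank_sd = null$rank_sd,
                      null_smaller_cox_p = null$n_random_smaller_cox_p),
      subtype = list(accuracy = sub$accuracy),
      enrichment = list(min_tf_p = min(reg$tf$fisher_p),
                        min_kd_p = min(reg$kd$fisher_p)),
      single_cell = list(summary = sc$summary)),
    checksums = as.list(setNames(unname(tools::md5sum(files)),
                                 basename(files))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
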