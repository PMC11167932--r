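# Synthetic cohorts with planted ground truth: every input the pipeline
# consumes can be generated offline, with the statistical structure the
# analysis assumes recorded in a truth table.

#' Simulation configuration
#'
#' Defaults define a cohort of 5,000 genes and 60 metastasis/primary
#' pairs with biopsy-site confounding (liver as the dominant-effect
#' site), 46 CRISPR-screened cell lines, a 1,000-sample survival cohort,
#' and cell-type-structured single-cell counts. All randomness flows
#' from the single `seed` through named substreams, one per output.
#'
#' @param n_genes number of genes.
#' @param n_patients number of metastasis/primary pairs.
#' @param sites named numeric: per-site fractions of metastasis samples
#'   (sums to 1).
#' @param dominant_site the site whose confounder effect is doubled
#'   (liver analogue).
#' @param role_fracs named fractions of genes per planted role
#'   (`intrinsic_met`, `site_confounder`, `breast_marker`, `cell_cycle`);
#'   the remainder is neutral.
#' @param delta_intrinsic,delta_site,delta_breast planted log2 effect
#'   sizes: the cancer-intrinsic metastasis effect, the per-site tissue
#'   effect (doubled at the dominant site), and the breast-marker drop in
#'   metastases.
#' @param noise_sd iid Gaussian noise SD on the log2 scale.
#' @param n_cell_lines number of cell lines in the effect-score matrix.
#' @param essential_fraction per-line probability that a planted
#'   essential gene scores below the essentiality threshold.
#' @param essential_noise_frac per-line probability that a non-essential
#'   gene scores below the threshold (0 = clean separation).
#' @param n_tissue_samples samples per tissue in the normal-tissue panel.
#' @param n_survival samples in the survival cohort.
#' @param beta planted log-hazard coefficient per unit signature score.
#' @param lambda loading of the shared signature activity on intrinsic
#'   genes in the survival cohort (coordinate expression).
#' @param censor_frac target censoring fraction.
#' @param n_subtypes,n_subtype_genes,subtype_sd planted molecular
#'   subtypes: number of subtypes, number of subtype-informative genes,
#'   and the SD of their centroid offsets (log2).
#' @param n_tfs,targets_per_tf,n_knockdowns,targets_per_knockdown planted
#'   regulator structure.
#' @param cell_types cell-type labels for the single-cell matrix; the
#'   first is the cancer-epithelial type, the second the non-cancer type
#'   that picks up the site-confounder genes.
#' @param n_cells_per_type cells per type.
#' @param sc_overexpression fold-change applied to planted genes in their
#'   overexpressing cell type.
#' @param sc_dispersion negative-binomial size parameter.
#' @param seed master seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       n_patients = 60,
                       sites = c(liver = 0.4, lung = 0.2, brain = 0.2,
                                 bone = 0.2),
                       dominant_site = "liver",
                       role_fracs = c(intrinsic_met = 0.05,
                                      site_confounder = 0.06,
                                      breast_marker = 0.04,
                                      cell_cycle = 0.04),
                       delta_intrinsic = 1,
                       delta_site = 1,
                       delta_breast = 1,
                       noise_sd = 0.5,
                       n_cell_lines = 46,
                       essential_fraction = 0.6,
                       essential_noise_frac = 0.01,
                       n_tissue_samples = 30,
                       n_survival = 1000,
                       beta = 0.5,
                       lambda = 1,
                       censor_frac = 0.3,
                       n_subtypes = 4,
                       n_subtype_genes = 300,
                       subtype_sd = 1,
                       n_tfs = 5,
                       targets_per_tf = 80,
                       n_knockdowns = 10,
                       targets_per_knockdown = 60,
                       cell_types = c("cancer_epithelial", "macrophage",
                                      "t_cell", "fibroblast"),
                       n_cells_per_type = 150,
                       sc_overexpression = 5,
                       sc_dispersion = 2,
                       seed = 1) {
  .assert(n_genes > 0 && n_patients > 0 && n_cell_lines > 0 &&
            n_survival > 0 && n_cells_per_type > 0,
          "all counts must be positive")
  .assert(abs(sum(sites) - 1) < 1e-8, "site fractions must sum to 1")
  .assert(dominant_site %in% names(sites), "dominant_site must be a site")
  .assert(sum(role_fracs) <= 1, "role fractions must sum to <= 1")
  .assert(all(is.finite(c(delta_intrinsic, delta_site, delta_breast,
                          noise_sd, beta, lambda))),
          "effect sizes must be finite")
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Planted ground truth for a simulation
#'
#' Assigns each gene a role, draws per-gene baseline log2 means
#' (Normal(5, 2), truncated below at 1.5 so TPM back-transform is
#' lossless), maps site-confounder genes to sites, plants subtype
#' centroid offsets, and plants TF-target and knockdown-target maps.
#'
#' @param config a [sim_config()].
#' @return list of class `truth_table`: `gene_role` (named), `site_map`
#'   (site -> genes), `baseline_log2` (named), `subtype_centroids`
#'   (genes x subtypes, nonzero only for subtype-informative genes),
#'   `tf_targets`, `kd_targets`, `effects`, `beta`, `lambda`, `seed`.
#' @export
make_truth <- function(config) {
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  withr::with_seed(.substream(config$seed, "truth"), {
    n_role <- round(config$role_fracs * config$n_genes)
    role <- rep("neutral", config$n_genes)
    idx <- sample.int(config$n_genes, sum(n_role))
    role[idx] <- rep(names(n_role), n_role)
    names(role) <- genes
    conf_genes <- genes[role == "site_confounder"]
    site_map <- split(conf_genes,
                      rep_len(names(config$sites), length(conf_genes)))
    baseline <- pmax(rnorm(config$n_genes, 5, 2), 1.5)
    names(baseline) <- genes
    subtypes <- paste0("subtype", seq_len(config$n_subtypes))
    centroids <- matrix(0, config$n_genes, config$n_subtypes,
                        dimnames = list(genes, subtypes))
    marker <- sample(genes[role == "neutral"],
                     min(config$n_subtype_genes, sum(role == "neutral")))
    centroids[marker, ] <- rnorm(length(marker) * config$n_subtypes,
                                 0, config$subtype_sd)
    tf_targets <- lapply(setNames(seq_len(config$n_tfs),
                                  paste0("TF", seq_len(config$n_tfs))),
                         function(i) sort(sample(genes,
                                                 config$targets_per_tf)))
    kd_targets <- lapply(setNames(seq_len(config$n_knockdowns),
                                  paste0("KD", seq_len(config$n_knockdowns))),
                         function(i) sort(sample(genes,
                                                 config$targets_per_knockdown)))
    structure(list(gene_role = role, site_map = site_map,
                   baseline_log2 = baseline,
                   subtype_centroids = centroids,
                   tf_targets = tf_targets, kd_targets = kd_targets,
                   effects = list(delta_intrinsic = config$delta_intrinsic,
                                  delta_site = config$delta_site,
                                  delta_breast = config$delta_breast,
                                  noise_sd = config$noise_sd),
                   beta = config$beta, lambda = config$lambda,
                   seed = config$seed, config = config),
              class = "truth_table")
  })
}

# Per-gene log2 effect added to a metastasis sample given its site.
# Site-confounder genes carry a shared non-breast-tissue component
# (delta_site / 2, present at every metastatic site, since every biopsy
# site is non-breast tissue) plus the full site-specific effect at their
# matching site (doubled at the dominant site).
.met_effect <- function(truth, site) {
  cfg <- truth$config
  eff <- numeric(length(truth$gene_role))
  names(eff) <- names(truth$gene_role)
  eff[truth$gene_role == "intrinsic_met"] <- cfg$delta_intrinsic
  eff[truth$gene_role == "site_confounder"] <- cfg$delta_site / 2
  d_site <- cfg$delta_site * ifelse(site == cfg$dominant_site, 2, 1)
  eff[truth$site_map[[site]]] <- eff[truth$site_map[[site]]] + d_site
  eff[truth$gene_role == "breast_marker"] <-
    eff[truth$gene_role == "breast_marker"] - cfg$delta_breast
  eff
}

#' Generate a paired metastasis/primary cohort (TPM units)
#'
#' Each patient's primary log2 profile is the gene baseline plus the
#' patient's planted-subtype centroid offsets plus Gaussian noise; the
#' metastasis profile adds the intrinsic effect on `intrinsic_met` genes,
#' the biopsy-site effect on confounder genes (a shared non-breast
#' component of `delta_site / 2` on every confounder gene — every biopsy
#' site is non-breast tissue — plus the full site effect on the matching
#' site's genes, doubled at the dominant site), subtracts the
#' breast-marker effect, and adds independent noise. Values are back-transformed to TPM as
#' `2^x - 1` clipped at 0.
#'
#' @param config a [sim_config()].
#' @param truth optional precomputed [make_truth()] (so several outputs
#'   share one truth).
#' @return list: `cohort` (a [paired_cohort()] in TPM units, annotation
#'   carrying patient, role, site, planted subtype) and `truth`.
#' @export
generate_paired_cohort <- function(config, truth = make_truth(config)) {
  cfg <- config
  genes <- names(truth$gene_role)
  withr::with_seed(.substream(cfg$seed, "paired_cohort"), {
    patients <- sprintf("p%03d", seq_len(cfg$n_patients))
    site <- sample(names(cfg$sites), cfg$n_patients, replace = TRUE,
                   prob = cfg$sites)
    subtype <- sample(colnames(truth$subtype_centroids), cfg$n_patients,
                      replace = TRUE)
    pri <- vapply(seq_len(cfg$n_patients), function(i)
      truth$baseline_log2 + truth$subtype_centroids[, subtype[i]] +
        rnorm(cfg$n_genes, 0, cfg$noise_sd),
      numeric(cfg$n_genes))
    met <- vapply(seq_len(cfg$n_patients), function(i)
      pri[, i] + .met_effect(truth, site[i]) +
        rnorm(cfg$n_genes, 0, cfg$noise_sd),
      numeric(cfg$n_genes))
    met_ids <- paste0(patients, "_met")
    pri_ids <- paste0(patients, "_pri")
    x <- cbind(met, pri)
    dimnames(x) <- list(genes, c(met_ids, pri_ids))
    tpm <- expression_matrix(pmax(2^x - 1, 0), "TPM")
    samples <- data.frame(
      sample = c(met_ids, pri_ids),
      patient = c(patients, patients),
      role = rep(c("metastasis", "primary"), each = cfg$n_patients),
      site = c(site, rep("breast", cfg$n_patients)),
      subtype = c(subtype, subtype),
      stringsAsFactors = FALSE)
    pairs <- data.frame(patient = patients, metastasis = met_ids,
                        primary = pri_ids, stringsAsFactors = FALSE)
    list(cohort = paired_cohort(tpm, samples, pairs), truth = truth)
  })
}

#' Generate a gene-effect (dependency) score matrix
#'
#' Planted essential genes (`intrinsic_met` and `cell_cycle` roles) score
#' below -0.75 in a Bernoulli(`essential_fraction`) majority of lines;
#' all other genes score below -0.75 only with probability
#' `essential_noise_frac` per line (0 = never). Essential calls draw from
#' Uniform(-2, -0.8), non-essential from Uniform(-0.6, 0.5), so the
#' -0.75 threshold separates them exactly at zero noise.
#'
#' @param truth a [make_truth()] truth table.
#' @param config the matching [sim_config()].
#' @return genes x cell-lines numeric matrix of Chronos-style scores.
#' @export
generate_effect_scores <- function(truth, config = truth$config) {
  genes <- names(truth$gene_role)
  essential_gene <- truth$gene_role %in% c("intrinsic_met", "cell_cycle")
  withr::with_seed(.substream(config$seed, "effect_scores"), {
    pr <- ifelse(essential_gene, config$essential_fraction,
                 config$essential_noise_frac)
    n <- config$n_cell_lines
    ess <- matrix(rbinom(length(genes) * n, 1, rep(pr, n)) == 1,
                  length(genes), n)
    val <- matrix(runif(length(genes) * n, -0.6, 0.5), length(genes), n)
    val[ess] <- runif(sum(ess), -2, -0.8)
    dimnames(val) <- list(genes, sprintf("line%02d", seq_len(n)))
    val
  })
}

#' Generate a normal-tissue expression panel (log2 units)
#'
#' One breast group plus one tissue group per metastatic site.
#' Breast-marker genes are elevated in breast by `delta_breast`; each
#' site's confounder genes are elevated in the matching non-breast
#' tissue by the site effect.
#'
#' @param truth a [make_truth()] truth table.
#' @param config the matching [sim_config()].
#' @return list: `panel` (expression matrix, log2 units) and `tissue`
#'   (label per sample).
#' @export
generate_normal_tissue_panel <- function(truth, config = truth$config) {
  genes <- names(truth$gene_role)
  tissues <- c("breast", names(config$sites))
  withr::with_seed(.substream(config$seed, "tissue_panel"), {
    cols <- list()
    labels <- character(0)
    for (ts in tissues) {
      eff <- numeric(length(genes))
      names(eff) <- genes
      if (ts == "breast") {
        eff[truth$gene_role == "breast_marker"] <- config$delta_breast
      } else {
        # confounder genes carry a shared non-breast-tissue component in
        # every non-breast tissue, plus the full effect in their own
        eff[truth$gene_role == "site_confounder"] <- config$delta_site / 2
        d <- config$delta_site * ifelse(ts == config$dominant_site, 2, 1)
        eff[truth$site_map[[ts]]] <- eff[truth$site_map[[ts]]] + d
      }
      m <- vapply(seq_len(config$n_tissue_samples), function(i)
        truth$baseline_log2 + eff + rnorm(length(genes), 0, config$noise_sd),
        numeric(length(genes)))
      cols[[ts]] <- m
      labels <- c(labels, rep(ts, config$n_tissue_samples))
    }
    x <- do.call(cbind, cols)
    dimnames(x) <- list(genes, sprintf("n%04d", seq_len(ncol(x))))
    list(panel = expression_matrix(x, "log2"), tissue = labels)
  })
}

#' Generate a primary-tumor survival cohort
#'
#' Per sample, a latent signature activity a ~ N(0, 1) loads with weight
#' `lambda` on every `intrinsic_met` gene (coordinate expression); all
#' genes also carry baseline plus Gaussian noise. Event times are
#' exponential with hazard proportional to `exp(beta * a)`; censoring is
#' independent exponential with its rate solved numerically so the
#' expected censoring fraction matches `censor_frac`.
#'
#' @param truth a [make_truth()] truth table.
#' @param config the matching [sim_config()].
#' @return list: `expr` (expression matrix, log2 units), `surv`
#'   (a [survival_table()]), `planted_score` (the latent activity per
#'   sample).
#' @export
generate_survival_cohort <- function(truth, config = truth$config) {
  genes <- names(truth$gene_role)
  intrinsic <- truth$gene_role == "intrinsic_met"
  withr::with_seed(.substream(config$seed, "survival_cohort"), {
    n <- config$n_survival
    a <- rnorm(n)
    x <- vapply(seq_len(n), function(i) {
      v <- truth$baseline_log2 + rnorm(length(genes), 0, config$noise_sd)
      v[intrinsic] <- v[intrinsic] + config$lambda * a[i]
      v
    }, numeric(length(genes)))
    ids <- sprintf("s%04d", seq_len(n))
    dimnames(x) <- list(genes, ids)
    rate <- 0.05 * exp(config$beta * a)
    t_event <- rexp(n, rate)
    cens_rate <- if (config$censor_frac <= 0) 0 else
      uniroot(function(mu) mean(mu / (mu + rate)) - config$censor_frac,
              c(1e-8, 1e4))$root
    t_cens <- if (cens_rate > 0) rexp(n, cens_rate) else rep(Inf, n)
    surv <- survival_table(ids, pmin(t_event, t_cens),
                           as.integer(t_event <= t_cens))
    list(expr = expression_matrix(x, "log2"), surv = surv,
         planted_score = setNames(a, ids))
  })
}

#' Generate gene loci, TF binding intervals, and a knockdown matrix
#'
#' Genes are tiled along one chromosome with alternating strands; each
#' planted TF target receives one binding interval uniformly inside the
#' gene's strand-aware 2 kb upstream window, plus decoy sites placed
#' where they intersect no window. Planted knockdown targets receive
#' standardized values in Uniform(-2, -0.8) (< -0.5) in their knockdown
#' column; all other entries are N(0, 0.2) truncated above -0.4.
#'
#' @param truth a [make_truth()] truth table.
#' @param config the matching [sim_config()].
#' @return list: `loci` (data.frame gene, chrom, start, end, strand;
#'   0-based half-open), `sites` (data.frame tf, chrom, start, end),
#'   `knockdown` (genes x knockdowns matrix, SD units).
#' @export
generate_regulator_data <- function(truth, config = truth$config) {
  genes <- names(truth$gene_role)
  n <- length(genes)
  window <- 2000L
  start <- 10000L * seq_len(n)
  loci <- data.frame(gene = genes, chrom = "chr1", start = start,
                     end = start + 1500L,
                     strand = rep_len(c("+", "-"), n),
                     stringsAsFactors = FALSE)
  withr::with_seed(.substream(config$seed, "regulator"), {
    site_rows <- lapply(names(truth$tf_targets), function(tf) {
      tg <- match(truth$tf_targets[[tf]], genes)
      w0 <- ifelse(loci$strand[tg] == "+", loci$start[tg] - window,
                   loci$end[tg])
      s <- w0 + sample.int(window - 50L, length(tg), replace = TRUE) - 1L
      decoy_g <- sample.int(n, length(tg) %/% 2L)
      decoy_s <- loci$start[decoy_g] + 4000L
      data.frame(tf = tf, chrom = "chr1",
                 start = c(s, decoy_s), end = c(s + 50L, decoy_s + 50L),
                 stringsAsFactors = FALSE)
    })
    sites <- do.call(rbind, site_rows)
    kd <- matrix(pmax(rnorm(n * config$n_knockdowns, 0, 0.2), -0.4),
                 n, config$n_knockdowns,
                 dimnames = list(genes, names(truth$kd_targets)))
    for (k in names(truth$kd_targets)) {
      tg <- truth$kd_targets[[k]]
      kd[tg, k] <- runif(length(tg), -2, -0.8)
    }
    list(loci = loci, sites = sites, knockdown = kd)
  })
}

#' Generate a cell-type-structured single-cell count matrix
#'
#' Negative-binomial counts with per-gene base means; the first cell type
#' (cancer epithelial) overexpresses the `intrinsic_met` genes by
#' `sc_overexpression`-fold, and the second cell type overexpresses the
#' dominant site's confounder genes by the same factor.
#'
#' @param truth a [make_truth()] truth table.
#' @param config the matching [sim_config()].
#' @return list: `counts` (genes x cells integer matrix), `cell_type`
#'   (label per cell).
#' @export
generate_single_cell <- function(truth, config = truth$config) {
  genes <- names(truth$gene_role)
  types <- config$cell_types
  withr::with_seed(.substream(config$seed, "single_cell"), {
    base_mu <- exp(rnorm(length(genes), log(2), 0.8))
    names(base_mu) <- genes
    cols <- list()
    labels <- character(0)
    for (ti in seq_along(types)) {
      mult <- rep(1, length(genes))
      if (ti == 1L)
        mult[truth$gene_role == "intrinsic_met"] <- config$sc_overexpression
      if (ti == 2L)
        mult[genes %in% truth$site_map[[config$dominant_site]]] <-
          config$sc_overexpression
      mu <- base_mu * mult
      m <- vapply(seq_len(config$n_cells_per_type), function(i)
        rnbinom(length(genes), mu = mu, size = config$sc_dispersion),
        numeric(length(genes)))
      cols[[ti]] <- m
      labels <- c(labels, rep(types[ti], config$n_cells_per_type))
    }
    x <- do.call(cbind, cols)
    dimnames(x) <- list(genes, sprintf("c%04d", seq_len(ncol(x))))
    list(counts = x, cell_type = labels)
  })
}

#' Generate a multi-study compendium of paired cohorts (log2 units)
#'
#' Smaller external-style paired cohorts sharing the same truth, each
#' with its own noise realization and a study-specific scale factor
#' applied to the log2 values (emulating inter-dataset unit
#' differences that pair-centering and SD-scaling must remove).
#'
#' @param truth a [make_truth()] truth table.
#' @param config the matching [sim_config()].
#' @param n_studies number of studies; default 3.
#' @param pairs_per_study pairs per study; default 20.
#' @return named list of [paired_cohort()]s in log2 units.
#' @export
generate_compendium <- function(truth, config = truth$config,
                                n_studies = 3, pairs_per_study = 20) {
  scales <- c(1, 2, 0.5, 1.5, 0.75)[seq_len(n_studies)]
  out <- lapply(seq_len(n_studies), function(j) {
    cfg <- config
    cfg$n_patients <- pairs_per_study
    cfg$seed <- .substream(config$seed, paste0("compendium", j))
    cc <- generate_paired_cohort(cfg, truth)$cohort
    x <- log2_transform(cc$expr, 1) * scales[j]
    x <- .set_units(x, "log2")
    prefix <- sprintf("study%d_", j)
    colnames(x) <- paste0(prefix, colnames(x))
    samples <- cc$samples
    samples$sample <- paste0(prefix, samples$sample)
    samples$patient <- paste0(prefix, samples$patient)
    samples$study <- paste0("study", j)
    pairs <- cc$pairs
    pairs$patient <- paste0(prefix, pairs$patient)
    pairs$metastasis <- paste0(prefix, pairs$metastasis)
    pairs$primary <- paste0(prefix, pairs$primary)
    paired_cohort(x, samples, pairs)
  })
  names(out) <- paste0("study", seq_len(n_studies))
  out
}
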