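#' Simulation configuration: pooled overexpression screen
#'
#' Defines the conditions of the synthetic pooled miR-Vec dropout screen: a
#' library of vectors sequenced at baseline (`Ctrl0`), after 30 days of normal
#' culture (`Ctrl30`) and after 30 days of EGFR-TKI treatment (`Gef30`), in
#' biological triplicate. Planted "enriched" vectors gain relative abundance
#' between `Ctrl0` and `Ctrl30` (increased proliferation); planted "depleted"
#' vectors lose abundance between `Ctrl30` and `Gef30` (drug sensitization).
#' A configurable number of hits (`n_dual`) belong to both classes, and every
#' planted hit miRNA carries the configured seed motif.
#'
#' @param n_vectors number of miR-Vec clones in the library.
#' @param conditions ordered condition labels; contrasts run between
#'   consecutive pairs by default.
#' @param n_replicates biological replicates per condition.
#' @param depth expected total reads per replicate library.
#' @param dispersion negative-binomial overdispersion phi; counts have
#'   variance mu + phi * mu^2 (phi = 0 gives Poisson counts).
#' @param n_enriched,n_depleted planted hit counts per class.
#' @param n_dual number of depleted hits that are also enriched hits
#'   (the dual proliferation + sensitization phenotype).
#' @param log2_effect_enrich,log2_effect_deplete planted effect sizes in log2
#'   units (both positive; depletion is applied as a negative fold).
#' @param motif planted seed k-mer over \{A, C, G, U\}, length <= 8.
#' @param abundance_sdlog sdlog of the log-normal baseline clone abundances.
#' @param plant_floor minimum expected baseline read count for a clone to be
#'   eligible as a planted hit; recovery experiments measure statistical
#'   recovery, not censoring of clones too shallow to ever pass read filters.
#' @param seed RNG seed; the generator is a pure function of the config.
#' @return object of class `screen_sim_config`.
#' @seealso [generate_screen()]
#' @export
screen_sim_config <- function(n_vectors = 450L,
                              conditions = c("Ctrl0", "Ctrl30", "Gef30"),
                              n_replicates = 3L,
                              depth = 1e6,
                              dispersion = 0.05,
                              n_enriched = 15L,
                              n_depleted = 15L,
                              n_dual = 8L,
                              log2_effect_enrich = 2.5,
                              log2_effect_deplete = 2.5,
                              motif = "AAGUGC",
                              abundance_sdlog = 1,
                              plant_floor = 600,
                              seed = 1L) {
  cfg <- list(
    n_vectors = as.integer(n_vectors), conditions = as.character(conditions),
    n_replicates = as.integer(n_replicates), depth = depth,
    dispersion = dispersion, n_enriched = as.integer(n_enriched),
    n_depleted = as.integer(n_depleted), n_dual = as.integer(n_dual),
    log2_effect_enrich = log2_effect_enrich,
    log2_effect_deplete = log2_effect_deplete,
    motif = toupper(motif), abundance_sdlog = abundance_sdlog,
    plant_floor = plant_floor, seed = .resolve_seed(seed)
  )
  stopifnot(
    cfg$n_vectors > 0L, length(cfg$conditions) >= 2L,
    !anyDuplicated(cfg$conditions), cfg$n_replicates >= 2L,
    is.finite(cfg$log2_effect_enrich), is.finite(cfg$log2_effect_deplete),
    cfg$dispersion >= 0, cfg$abundance_sdlog >= 0,
    cfg$n_enriched >= 0L, cfg$n_depleted >= 0L,
    cfg$n_dual >= 0L, cfg$n_dual <= min(cfg$n_enriched, cfg$n_depleted),
    cfg$n_enriched + cfg$n_depleted <= cfg$n_vectors
  )
  if (cfg$depth <= 0) stop("'depth' must be positive")
  if (nchar(cfg$motif) > 8L) {
    stop("'motif' must fit within the 8-nt seed region")
  }
  if (grepl("[^ACGU]", cfg$motif)) {
    stop("'motif' must be over the alphabet {A, C, G, U}")
  }
  structure(cfg, class = "screen_sim_config")
}

#' Simulation configuration: mimic-transfection omics experiment
#'
#' Defines a paired mRNA + protein differential experiment: triplicate
#' mimic-transfected vs control cultures measured as per-gene log2 abundances,
#' with planted target genes repressed in the mimic arm and prediction counts
#' (number of algorithms, out of 9, nominating each gene) stochastically
#' elevated for targets.
#'
#' @param n_genes gene universe size.
#' @param n_targets planted target count.
#' @param n_replicates replicates per arm.
#' @param delta_mrna,delta_protein mean log2 repression of true targets
#'   (non-positive).
#' @param noise_sd replicate noise standard deviation (log2 units).
#' @param protein_coverage fraction of genes observed at the protein level.
#' @param pred_p_target,pred_p_null per-algorithm prediction probability for
#'   targets and non-targets (9 algorithms).
#' @param n_algorithms number of prediction algorithms.
#' @param seed RNG seed.
#' @return object of class `omics_sim_config`.
#' @seealso [generate_omics()]
#' @export
omics_sim_config <- function(n_genes = 12000L,
                             n_targets = 500L,
                             n_replicates = 3L,
                             delta_mrna = -1,
                             delta_protein = -1,
                             noise_sd = 0.3,
                             protein_coverage = 0.7,
                             pred_p_target = 0.7,
                             pred_p_null = 0.1,
                             n_algorithms = 9L,
                             seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_targets = as.integer(n_targets),
    n_replicates = as.integer(n_replicates), delta_mrna = delta_mrna,
    delta_protein = delta_protein, noise_sd = noise_sd,
    protein_coverage = protein_coverage, pred_p_target = pred_p_target,
    pred_p_null = pred_p_null, n_algorithms = as.integer(n_algorithms),
    seed = .resolve_seed(seed)
  )
  stopifnot(
    cfg$n_genes > 0L, cfg$n_targets >= 0L, cfg$n_targets <= cfg$n_genes,
    cfg$n_replicates >= 2L, cfg$delta_mrna <= 0, cfg$delta_protein <= 0,
    cfg$noise_sd > 0, cfg$n_algorithms >= 1L,
    cfg$pred_p_target >= 0, cfg$pred_p_target <= 1,
    cfg$pred_p_null >= 0, cfg$pred_p_null <= 1
  )
  if (cfg$protein_coverage < 0 || cfg$protein_coverage > 1) {
    stop("'protein_coverage' must lie in [0, 1]")
  }
  structure(cfg, class = "omics_sim_config")
}

#' Simulation configuration: tumor cohort with latent oncomotif activity
#'
#' Defines a TCGA-like cohort in which one latent per-sample activity couples
#' everything the downstream analysis looks for: seed-family miRNA expression
#' rises with activity, tumor-suppressor (TS) genes are repressed, cell-cycle
#' genes induced, TP53-mutation probability increases on the logistic scale,
#' and relapse hazard grows exponentially. Normal samples sit at an activity
#' offset of -2 relative to tumors, so they co-cluster with low-activity
#' tumors.
#'
#' @param n_tumors,n_normals sample counts.
#' @param n_family_mirnas seed-family (oncomotif) miRNA count.
#' @param n_other_mirnas background miRNAs included so that reads-per-million
#'   normalization is non-trivial.
#' @param ts_genes labelled tumor-suppressor panel (default: the curated
#'   seven-gene panel).
#' @param n_cellcycle,n_null induced cell-cycle and uncoupled null gene counts.
#' @param beta_ts,beta_cc coupling magnitudes of activity to TS (applied
#'   negatively) and cell-cycle (positively) gene expression, log2 units per
#'   activity unit.
#' @param mirna_coupling log-scale coupling of family miRNA expression to
#'   activity.
#' @param mut_base,mut_slope logistic intercept/slope linking activity to
#'   TP53-mutation probability (MYC gain uses the same link at half slope).
#' @param hazard_slope log relapse hazard per unit activity.
#' @param base_hazard baseline exponential relapse rate (per year).
#' @param censor_rate probability a tumor's relapse time is uniformly
#'   right-censored; in \[0, 1).
#' @param normal_offset latent-activity shift of normal samples.
#' @param normal_sd residual activity spread of normal samples; smaller than
#'   the tumors' unit spread because normal tissue does not span the tumor
#'   activity continuum.
#' @param noise_sd residual expression noise (log2 units).
#' @param cancer_type label attached to the dataset.
#' @param seed RNG seed.
#' @return object of class `cohort_sim_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_sim_config <- function(n_tumors = 400L,
                              n_normals = 20L,
                              n_family_mirnas = 28L,
                              n_other_mirnas = 300L,
                              ts_genes = c("TGFBR2", "CDKN1A", "LATS2",
                                           "RBL2", "ZBTB7A", "PTEN", "RB1"),
                              n_cellcycle = 50L,
                              n_null = 500L,
                              beta_ts = 0.8,
                              beta_cc = 0.8,
                              mirna_coupling = 0.7,
                              mut_base = -0.5,
                              mut_slope = 1,
                              hazard_slope = 0.8,
                              base_hazard = 0.15,
                              censor_rate = 0.3,
                              normal_offset = -2,
                              normal_sd = 0.5,
                              noise_sd = 0.5,
                              cancer_type = "SYN",
                              seed = 1L) {
  cfg <- list(
    n_tumors = as.integer(n_tumors), n_normals = as.integer(n_normals),
    n_family_mirnas = as.integer(n_family_mirnas),
    n_other_mirnas = as.integer(n_other_mirnas),
    ts_genes = as.character(ts_genes),
    n_cellcycle = as.integer(n_cellcycle), n_null = as.integer(n_null),
    beta_ts = beta_ts, beta_cc = beta_cc, mirna_coupling = mirna_coupling,
    mut_base = mut_base, mut_slope = mut_slope,
    hazard_slope = hazard_slope, base_hazard = base_hazard,
    censor_rate = censor_rate, normal_offset = normal_offset,
    normal_sd = normal_sd, noise_sd = noise_sd, cancer_type = as.character(cancer_type),
    seed = .resolve_seed(seed)
  )
  if (cfg$n_tumors <= 0L || cfg$n_normals < 0L) {
    stop("sample counts must be positive")
  }
  stopifnot(
    cfg$n_family_mirnas >= 1L, cfg$n_other_mirnas >= 0L,
    length(cfg$ts_genes) >= 1L, !anyDuplicated(cfg$ts_genes),
    cfg$n_cellcycle >= 0L, cfg$n_null >= 0L,
    is.finite(cfg$beta_ts), is.finite(cfg$beta_cc),
    is.finite(cfg$mut_slope), is.finite(cfg$hazard_slope),
    cfg$base_hazard > 0, cfg$noise_sd > 0, cfg$normal_sd > 0,
    cfg$censor_rate >= 0, cfg$censor_rate < 1
  )
  structure(cfg, class = "cohort_sim_config")
}
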