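#' Run the full simulate-and-analyze pipeline
#'
#' Orchestrates the whole inference chain on synthetic data: simulate a
#' pooled screen, a mimic-vs-control omics experiment and a tumor cohort;
#' run screen enrichment/depletion analysis and intersect the proliferation
#' and sensitization hits; discover the shared seed motif among the dual
#' hits; integrate mRNA/protein/prediction evidence into putative target
#' calls; derive the cohort signature with clustering, genotype association
#' and survival analysis; and profile miRNA-mRNA correlations. Each stage
#' writes its tables under a stage subdirectory of `out_dir`, along with a
#' resolved-config JSON and a log recording stage, seed and input checksums.
#' All randomness flows from `seed` (expanded per generator), so a rerun
#' with identical arguments reproduces every output file.
#'
#' @param out_dir output directory (created if needed).
#' @param seed top-level RNG seed.
#' @param screen_cfg,omics_cfg,cohort_cfg generator configs; defaults are
#'   built from `seed` with the documented per-stage offsets (0, 1000, 2000).
#' @param use_protein include the protein layer in target evidence
#'   (disabling it degrades the calls to mRNA-only, with a warning).
#' @param min_reads,lfc_threshold,p_threshold screen analysis parameters.
#' @param motif_k shared-motif length.
#' @param min_predictions,target_p target-call parameters.
#' @param pct,fdr_threshold,sig_lfc_threshold signature parameters.
#' @param inverse_threshold inverse-correlation cutoff.
#' @return invisible list with the main per-stage results.
#' @export
run_pipeline <- function(out_dir,
                         seed = 1L,
                         screen_cfg = NULL,
                         omics_cfg = NULL,
                         cohort_cfg = NULL,
                         use_protein = TRUE,
                         min_reads = 300,
                         lfc_threshold = 1.5,
                         p_threshold = 0.05,
                         motif_k = 6L,
                         min_predictions = 5L,
                         target_p = 0.05,
                         pct = 5,
                         fdr_threshold = 1e-5,
                         sig_lfc_threshold = 1,
                         inverse_threshold = -0.15) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(stage, ...) {
    writeLines(sprintf("[%s] seed=%d %s", stage, seed,
                       paste0(...)), log_con)
  }
  stage_dir <- function(name) {
    d <- file.path(out_dir, name)
    dir.create(d, showWarnings = FALSE)
    d
  }
  checksum <- function(paths) {
    paste(sprintf("%s=%s", basename(paths), unname(tools::md5sum(paths))),
          collapse = " ")
  }

  if (is.null(screen_cfg)) screen_cfg <- screen_sim_config(seed = seed)
  if (is.null(omics_cfg)) {
    omics_cfg <- omics_sim_config(seed = .resolve_seed(seed, 1000L))
  }
  if (is.null(cohort_cfg)) {
    cohort_cfg <- cohort_sim_config(seed = .resolve_seed(seed, 2000L))
  }

  resolved <- list(
    seed = seed, screen = unclass(screen_cfg), omics = unclass(omics_cfg),
    cohort = unclass(cohort_cfg),
    analysis = list(
      use_protein = use_protein, min_reads = min_reads,
      lfc_threshold = lfc_threshold, p_threshold = p_threshold,
      motif_k = motif_k, min_predictions = min_predictions,
      target_p = target_p, pct = pct, fdr_threshold = fdr_threshold,
      sig_lfc_threshold = sig_lfc_threshold,
      inverse_threshold = inverse_threshold
    )
  )
  jsonlite::write_json(resolved, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # ---- simulate -----------------------------------------------------------
  d <- stage_dir("simulate")
  scr <- generate_screen(screen_cfg)
  omx <- generate_omics(omics_cfg)
  coh <- generate_cohort(cohort_cfg)
  write_matrix(scr$table$counts, file.path(d, "screen_counts.tsv"))
  write_fasta(scr$catalogue, file.path(d, "catalogue.fasta"))
  write_matrix(omx$mrna, file.path(d, "mrna.tsv"))
  write_matrix(omx$protein, file.path(d, "protein.tsv"))
  utils::write.table(omx$predictions, file.path(d, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix(coh$cohort$mirna, file.path(d, "cohort_mirna.tsv"))
  write_matrix(coh$cohort$mrna, file.path(d, "cohort_mrna.tsv"))
  utils::write.table(coh$cohort$meta, file.path(d, "cohort_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(screen = scr$truth[setdiff(names(scr$truth), "expected_mu")],
         omics = omx$truth,
         cohort = coh$truth[c("family_mirnas", "ts_genes",
                              "cellcycle_genes", "seed_used")]),
    file.path(d, "truth.json"), auto_unbox = TRUE, digits = NA)
  say("simulate", checksum(list.files(d, full.names = TRUE)))

  # ---- screen -------------------------------------------------------------
  d <- stage_dir("screen")
  enr <- screen_enrichment(scr$table, min_reads = min_reads,
                           lfc_threshold = lfc_threshold,
                           p_threshold = p_threshold)
  utils::write.table(enr, file.path(d, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  conds <- unique(scr$table$design$condition)
  tag1 <- paste0(conds[2], "_vs_", conds[1])
  tag2 <- paste0(conds[3], "_vs_", conds[2])
  prolif <- enr$vector_id[!is.na(enr[[paste0("class_", tag1)]]) &
                            enr[[paste0("class_", tag1)]] == "enriched"]
  sensit <- enr$vector_id[!is.na(enr[[paste0("class_", tag2)]]) &
                            enr[[paste0("class_", tag2)]] == "depleted"]
  dual <- intersect_hits(prolif, sensit)
  writeLines(dual, file.path(d, "dual_hits.txt"))
  say("screen", sprintf("enriched=%d depleted=%d dual=%d",
                        length(prolif), length(sensit), length(dual)))

  # ---- motif --------------------------------------------------------------
  d <- stage_dir("motif")
  hit_set <- if (length(dual) > 0L) dual else unique(c(prolif, sensit))
  motif_tab <- NULL
  family <- NULL
  if (length(hit_set) > 0L) {
    motif_tab <- find_shared_motifs(hit_set, scr$catalogue, k = motif_k)
    utils::write.table(motif_tab, file.path(d, "motif_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    family <- assign_seed_family(scr$catalogue, motif_tab$motif[1L])
    utils::write.table(family$members, file.path(d, "seed_family.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    say("motif", sprintf("top_motif=%s family_size=%d",
                         motif_tab$motif[1L], nrow(family$members)))
  } else {
    say("motif", "no hits; stage skipped")
  }

  # ---- targets ------------------------------------------------------------
  d <- stage_dir("targets")
  arm <- function(m, prefix) m[, grep(prefix, colnames(m)), drop = FALSE]
  mrna_diff <- differential_table(arm(omx$mrna, "^mimic"),
                                  arm(omx$mrna, "^ctrl"))
  protein_diff <- if (use_protein) {
    differential_table(arm(omx$protein, "^mimic"), arm(omx$protein, "^ctrl"))
  } else NULL
  if (!use_protein) say("targets", "protein layer disabled; mRNA-only evidence")
  evidence <- call_putative_targets(
    build_evidence_table(mrna_diff, protein_diff, omx$predictions),
    p_threshold = target_p, min_predictions = min_predictions
  )
  utils::write.table(evidence, file.path(d, "evidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  shift <- ecdf_shift(evidence$mrna_log2fc, evidence$stratum)
  utils::write.table(shift$tests, file.path(d, "ecdf_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("targets", sprintf("putative_targets=%d", sum(evidence$putative_target)))

  # ---- signature ----------------------------------------------------------
  d <- stage_dir("signature")
  sums <- sum_family_expression(coh$cohort$mirna, coh$cohort$family_ids)
  tumor_ids <- coh$cohort$meta$sample_id[coh$cohort$meta$is_tumor]
  groups <- percentile_groups(sums[tumor_ids], pct = pct)
  sig <- derive_signature(coh$cohort$mrna, groups$high, groups$low,
                          fdr_threshold = fdr_threshold,
                          lfc_threshold = sig_lfc_threshold)
  utils::write.table(sig$table, file.path(d, "signature.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cluster_genes <- if (length(sig$genes) >= 2L) sig$genes else NULL
  if (is.null(cluster_genes)) {
    say("signature", "fewer than 2 signature genes; clustering on all genes")
  }
  cl <- hierarchical_cluster(coh$cohort$mrna, genes = cluster_genes)
  labels <- label_clusters(cl$clusters, sums)
  utils::write.table(
    data.frame(sample_id = names(cl$clusters), cluster = labels),
    file.path(d, "clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  meta <- coh$cohort$meta
  tum <- meta$is_tumor
  wil <- genotype_association(sums[meta$sample_id[tum]],
                              meta$TP53_mut[tum])
  km <- km_logrank(meta$rfs_time[tum], meta$rfs_event[tum],
                   labels[match(meta$sample_id[tum], names(labels))])
  utils::write.table(km$curves, file.path(d, "km_curves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cox <- cox_regression(
    meta$rfs_time[tum], meta$rfs_event[tum],
    data.frame(
      cluster = labels[match(meta$sample_id[tum], names(labels))],
      TP53_mut = factor(meta$TP53_mut[tum]),
      MYC_gain = factor(meta$MYC_gain[tum])
    )
  )
  jsonlite::write_json(
    list(n_signature_genes = length(sig$genes),
         wilcoxon_tp53_p = wil$p_value,
         logrank_p = km$p_value,
         cox = cox$table),
    file.path(d, "survival_summary.json"), auto_unbox = TRUE, digits = NA)
  say("signature", sprintf("genes=%d logrank_p=%.3g", length(sig$genes),
                           km$p_value))

  # ---- network ------------------------------------------------------------
  d <- stage_dir("network")
  profile <- correlate_genes(sums, coh$cohort$mrna)
  utils::write.table(profile, file.path(d, "correlation_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  inverse <- call_inverse_targets(profile, threshold = inverse_threshold,
                                  candidate_set = coh$truth$ts_genes)
  writeLines(inverse, file.path(d, "inverse_targets.txt"))
  ranking <- rank_cancers_by_ts_correlation(
    stats::setNames(list(profile), coh$cohort$cancer_type),
    coh$truth$ts_genes
  )
  utils::write.table(ranking, file.path(d, "ts_ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("network", sprintf("inverse_ts=%d/%d median_rpm=%.0f",
                         length(inverse), length(coh$truth$ts_genes),
                         median_family_rpm(coh$cohort$mirna,
                                           coh$cohort$family_ids)))

  invisible(list(
    screen = list(result = enr, prolif = prolif, sensit = sensit,
                  dual = dual, truth = scr$truth),
    motif = list(table = motif_tab, family = family),
    targets = list(evidence = evidence, shift = shift, truth = omx$truth),
    signature = list(signature = sig, clusters = labels, wilcoxon = wil,
                     km = km, cox = cox, sums = sums, truth = coh$truth),
    network = list(profile = profile, inverse = inverse, ranking = ranking)
  ))
}
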