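#' Simulate a mimic-vs-control mRNA + protein experiment
#'
#' Generates per-gene log2 abundance matrices for a mimic-transfected arm and
#' a control arm at the mRNA level and, for a `protein_coverage` fraction of
#' genes, at the protein level, together with a per-gene prediction-count
#' table. Replicate values are Normal around a gene baseline with
#' `noise_sd`; planted targets have their mimic-arm mean shifted by
#' `delta_mrna` (`delta_protein` where observed). Prediction counts are
#' Binomial(`n_algorithms`, p) with p = `pred_p_target` for planted targets
#' and `pred_p_null` otherwise.
#'
#' @param cfg an [omics_sim_config()].
#' @return list with elements `mrna` and `protein` (log2 matrices, genes in
#'   rows, columns `mimic_rep*` then `ctrl_rep*`; `protein` may cover a subset
#'   of genes), `predictions` (data.frame `gene_id`, `prediction_count`), and
#'   `truth` (list with `target_ids`, `seed_used`).
#' @examples
#' sim <- generate_omics(omics_sim_config(n_genes = 100, n_targets = 10))
#' head(sim$predictions)
#' @export
generate_omics <- function(cfg) {
  stopifnot(inherits(cfg, "omics_sim_config"))
  withr::with_seed(cfg$seed, {
    genes <- sprintf("gene-%05d", seq_len(cfg$n_genes))
    targets <- sort(sample.int(cfg$n_genes, cfg$n_targets))
    is_target <- seq_len(cfg$n_genes) %in% targets

    arm_cols <- function(prefix) {
      sprintf("%s_rep%d", prefix, seq_len(cfg$n_replicates))
    }

    make_layer <- function(idx, delta) {
      ng <- length(idx)
      baseline <- stats::rnorm(ng, mean = 6, sd = 1.5)
      mu_case <- baseline + ifelse(is_target[idx], delta, 0)
      nrep <- cfg$n_replicates
      noise <- function() {
        matrix(stats::rnorm(ng * nrep, sd = cfg$noise_sd), ng, nrep)
      }
      m <- cbind(mu_case + noise(), baseline + noise())
      dimnames(m) <- list(genes[idx], c(arm_cols("mimic"), arm_cols("ctrl")))
      m
    }

    mrna <- make_layer(seq_len(cfg$n_genes), cfg$delta_mrna)
    n_prot <- round(cfg$protein_coverage * cfg$n_genes)
    prot_idx <- sort(sample.int(cfg$n_genes, n_prot))
    protein <- make_layer(prot_idx, cfg$delta_protein)

    pred_p <- ifelse(is_target, cfg$pred_p_target, cfg$pred_p_null)
    predictions <- data.frame(
      gene_id = genes,
      prediction_count = stats::rbinom(cfg$n_genes, cfg$n_algorithms, pred_p)
    )

    list(
      mrna = mrna,
      protein = protein,
      predictions = predictions,
      truth = list(target_ids = genes[targets], seed_used = cfg$seed)
    )
  })
}
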