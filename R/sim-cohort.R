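#' Simulate a tumor cohort with latent oncomotif activity
#'
#' Generates a paired miRNA/mRNA expression cohort driven by one latent
#' per-sample activity `a`: standard Normal for tumors; normal samples sit
#' at `normal_offset` with the tighter residual spread `normal_sd` (normal
#' tissue does not span the tumor activity continuum). Seed-family miRNA expression increases
#' monotonically with `a` (log-linear with slope `mirna_coupling`) before the
#' miRNA matrix is rescaled so every sample column sums to one million
#' (reads per million miRNA reads mapped). Tumor-suppressor genes are
#' repressed by `beta_ts * a`, cell-cycle genes induced by `beta_cc * a`,
#' and null genes carry noise only. TP53 mutation is Bernoulli with logistic
#' probability `plogis(mut_base + mut_slope * a)` (MYC gain uses half the
#' slope), and tumor relapse times are exponential with rate
#' `base_hazard * exp(hazard_slope * a)`, a `censor_rate` fraction uniformly
#' right-censored. Normal samples carry NA survival fields.
#'
#' @param cfg a [cohort_sim_config()].
#' @return list with elements `cohort` (list with `mirna` and `mrna` matrices,
#'   features in rows and samples in columns; `meta` data.frame with columns
#'   `sample_id`, `is_tumor`, `TP53_mut`, `MYC_gain`, `rfs_time`, `rfs_event`;
#'   `family_ids`; `cancer_type`) and `truth` (list with per-sample `activity`,
#'   gene/miRNA id sets and `seed_used`).
#' @examples
#' sim <- generate_cohort(cohort_sim_config(n_tumors = 50, n_normals = 5))
#' colSums(sim$cohort$mirna)[1:3]
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_tumors + cfg$n_normals
    sample_id <- c(sprintf("tumor-%04d", seq_len(cfg$n_tumors)),
                   sprintf("normal-%04d", seq_len(cfg$n_normals)))
    is_tumor <- rep(c(TRUE, FALSE), c(cfg$n_tumors, cfg$n_normals))
    activity <- ifelse(is_tumor,
                       stats::rnorm(n),
                       cfg$normal_offset + cfg$normal_sd * stats::rnorm(n))
    names(activity) <- sample_id

    # miRNA layer: family members span a decreasing baseline (one member
    # dominating, as seen for real seed families) and share the activity
    # coupling; background miRNAs are uncoupled.
    fam_ids <- sprintf("fam-mir-%02d", seq_len(cfg$n_family_mirnas))
    bg_ids <- sprintf("bg-mir-%03d", seq_len(cfg$n_other_mirnas))
    fam_base <- seq(log(3000), log(30), length.out = cfg$n_family_mirnas)
    bg_base <- stats::rnorm(cfg$n_other_mirnas, mean = log(2000), sd = 1.2)

    ln_noise <- function(nr) {
      matrix(stats::rnorm(nr * n, sd = 0.3), nr, n)
    }
    fam_raw <- exp(outer(fam_base, cfg$mirna_coupling * activity, `+`) +
                     ln_noise(cfg$n_family_mirnas))
    bg_raw <- exp(matrix(bg_base, cfg$n_other_mirnas, n) +
                    ln_noise(cfg$n_other_mirnas))
    mirna <- rbind(fam_raw, bg_raw)
    dimnames(mirna) <- list(c(fam_ids, bg_ids), sample_id)
    mirna <- sweep(mirna, 2L, colSums(mirna), `/`) * 1e6

    # mRNA layer (log2 fpkm-like)
    cc_ids <- sprintf("CC-%03d", seq_len(cfg$n_cellcycle))
    null_ids <- sprintf("G-%04d", seq_len(cfg$n_null))
    gene_ids <- c(cfg$ts_genes, cc_ids, null_ids)
    coupling <- c(rep(-cfg$beta_ts, length(cfg$ts_genes)),
                  rep(cfg$beta_cc, cfg$n_cellcycle),
                  rep(0, cfg$n_null))
    baseline <- stats::rnorm(length(gene_ids), mean = 6, sd = 1.5)
    mrna <- matrix(baseline, length(gene_ids), n) +
      outer(coupling, activity) +
      matrix(stats::rnorm(length(gene_ids) * n, sd = cfg$noise_sd),
             length(gene_ids), n)
    dimnames(mrna) <- list(gene_ids, sample_id)

    tp53 <- stats::rbinom(n, 1L, stats::plogis(cfg$mut_base +
                                                 cfg$mut_slope * activity))
    myc <- stats::rbinom(n, 1L, stats::plogis(cfg$mut_base +
                                                cfg$mut_slope / 2 * activity))

    rfs_time <- rep(NA_real_, n)
    rfs_event <- rep(NA_integer_, n)
    tum <- which(is_tumor)
    t_raw <- stats::rexp(length(tum),
                         rate = cfg$base_hazard *
                           exp(cfg$hazard_slope * activity[tum]))
    censored <- stats::runif(length(tum)) < cfg$censor_rate
    rfs_time[tum] <- ifelse(censored, stats::runif(length(tum)) * t_raw, t_raw)
    rfs_event[tum] <- as.integer(!censored)

    meta <- data.frame(
      sample_id = sample_id,
      is_tumor = is_tumor,
      TP53_mut = tp53,
      MYC_gain = myc,
      rfs_time = rfs_time,
      rfs_event = rfs_event
    )

    list(
      cohort = list(mirna = mirna, mrna = mrna, meta = meta,
                    family_ids = fam_ids, cancer_type = cfg$cancer_type),
      truth = list(
        activity = activity,
        family_mirnas = fam_ids,
        ts_genes = cfg$ts_genes,
        cellcycle_genes = cc_ids,
        null_genes = null_ids,
        seed_used = cfg$seed
      )
    )
  })
}
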