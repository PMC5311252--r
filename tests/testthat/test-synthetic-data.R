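test_that("generators are pure functions of their configs", {
  s1 <- generate_screen(screen_sim_config(n_vectors = 60, seed = 1))
  s2 <- generate_screen(screen_sim_config(n_vectors = 60, seed = 1))
  expect_identical(s1, s2)
  s3 <- generate_screen(screen_sim_config(n_vectors = 60, seed = 2))
  expect_false(identical(s1$table$counts, s3$table$counts))

  o1 <- generate_omics(omics_sim_config(n_genes = 200, n_targets = 20, seed = 5))
  o2 <- generate_omics(omics_sim_config(n_genes = 200, n_targets = 20, seed = 5))
  expect_identical(o1, o2)

  c1 <- generate_cohort(cohort_sim_config(n_tumors = 40, n_normals = 4, seed = 9))
  c2 <- generate_cohort(cohort_sim_config(n_tumors = 40, n_normals = 4, seed = 9))
  expect_identical(c1, c2)
})

test_that("screen generator plants the configured structure", {
  cfg <- screen_sim_config(seed = 3)
  sim <- generate_screen(cfg)
  tr <- sim$truth
  expect_length(tr$enriched_ids, cfg$n_enriched)
  expect_length(tr$depleted_ids, cfg$n_depleted)
  expect_identical(tr$dual_ids, intersect(tr$enriched_ids, tr$depleted_ids))
  expect_length(tr$dual_ids, cfg$n_dual)

  # planted hits carry the motif within the seed; background is motif-free
  seeds <- extract_seed(sim$catalogue$sequence)
  names(seeds) <- sim$catalogue$mirna_id
  hits <- union(tr$enriched_ids, tr$depleted_ids)
  expect_true(all(grepl(cfg$motif, seeds[hits], fixed = TRUE)))
  expect_false(any(grepl(cfg$motif, seeds[setdiff(names(seeds), hits)],
                         fixed = TRUE)))

  # the planted effects move expected abundance in the documented direction
  mu <- tr$expected_mu
  expect_true(all(mu[tr$enriched_ids, "Ctrl30"] > mu[tr$enriched_ids, "Ctrl0"]))
  expect_true(all(mu[tr$depleted_ids, "Gef30"] < mu[tr$depleted_ids, "Ctrl30"]))

  expect_true(all(sim$table$counts >= 0))
  expect_true(all(sim$table$counts == round(sim$table$counts)))
})

test_that("null screen config leaves expected abundance flat across conditions", {
  sim <- generate_screen(screen_sim_config(n_enriched = 0, n_depleted = 0,
                                           n_dual = 0, seed = 4))
  expect_length(sim$truth$enriched_ids, 0)
  mu <- sim$truth$expected_mu
  expect_equal(mu[, "Ctrl30"], mu[, "Ctrl0"], tolerance = 1e-12)
  expect_equal(mu[, "Gef30"], mu[, "Ctrl0"], tolerance = 1e-12)
})

test_that("replicate column totals sit within 5 SD of the NB total", {
  cfg <- screen_sim_config(n_vectors = 450, depth = 1e6, seed = 3)
  sim <- generate_screen(cfg)
  mu <- sim$truth$expected_mu
  for (cond in cfg$conditions) {
    total_mean <- sum(mu[, cond])
    expect_equal(total_mean, cfg$depth, tolerance = 1e-9)
    total_sd <- sqrt(sum(mu[, cond] + cfg$dispersion * mu[, cond]^2))
    cols <- grep(cond, colnames(sim$table$counts))
    expect_true(all(abs(colSums(sim$table$counts[, cols]) - total_mean)
                    < 5 * total_sd))
  }
})

test_that("screen config rejects invalid settings", {
  expect_error(screen_sim_config(depth = 0), "depth")
  expect_error(screen_sim_config(motif = "AAGUGCAAA"), "seed region")
  expect_error(screen_sim_config(motif = "AAGTGC"), "alphabet")
  expect_error(screen_sim_config(n_vectors = 20, n_enriched = 15,
                                 n_depleted = 15, n_dual = 0))
})

test_that("omics generator honours coverage and prediction model", {
  # full protein coverage covers every gene
  o <- generate_omics(omics_sim_config(n_genes = 150, n_targets = 15,
                                       protein_coverage = 1, seed = 2))
  expect_setequal(rownames(o$protein), rownames(o$mrna))

  # high-consensus tail of targets matches the exact binomial tail
  cfg <- omics_sim_config(n_genes = 8000, n_targets = 4000,
                          pred_p_target = 0.7, pred_p_null = 0.1, seed = 6)
  o <- generate_omics(cfg)
  is_t <- o$predictions$gene_id %in% o$truth$target_ids
  frac <- mean(o$predictions$prediction_count[is_t] >= 5)
  tail_p <- 1 - pbinom(4, 9, 0.7)   # oracle: exact binomial tail
  expect_lt(abs(frac - tail_p), 4 * sqrt(tail_p * (1 - tail_p) / sum(is_t)))

  expect_error(generate_omics(omics_sim_config(protein_coverage = 1.5)),
               "protein_coverage")
})

test_that("null omics effects leave targets indistinguishable", {
  o <- generate_omics(omics_sim_config(n_genes = 3000, n_targets = 1500,
                                       delta_mrna = 0, delta_protein = 0,
                                       seed = 8))
  diff <- differential_table(o$mrna[, 1:3], o$mrna[, 4:6])
  is_t <- diff$gene_id %in% o$truth$target_ids
  # group-mean fold changes of targets and non-targets identically
  # distributed: two-sample test should find nothing
  expect_gt(t.test(diff$log2fc[is_t], diff$log2fc[!is_t])$p.value, 0.001)
  expect_gt(ks.test(diff$log2fc[is_t], diff$log2fc[!is_t])$p.value, 0.001)
})

test_that("cohort miRNA columns are RPM-normalized and truth is coupled", {
  sim <- generate_cohort(cohort_sim_config(n_tumors = 400, hazard_slope = 0.8,
                                           seed = 7))
  expect_equal(colSums(sim$cohort$mirna),
               setNames(rep(1e6, ncol(sim$cohort$mirna)),
                        colnames(sim$cohort$mirna)),
               tolerance = 1e-6)

  # higher activity -> shorter relapse time (rank correlation on truth)
  meta <- sim$cohort$meta
  tum <- meta$is_tumor
  expect_lt(cor(sim$truth$activity[meta$sample_id[tum]],
                meta$rfs_time[tum], method = "kendall"), 0)

  # normals sit below tumors on the latent scale
  expect_lt(mean(sim$truth$activity[!tum]), mean(sim$truth$activity[tum]))

  # survival fields only for tumors
  expect_true(all(is.na(meta$rfs_time[!tum])))
  expect_true(all(meta$rfs_time[tum] > 0))
})

test_that("decoupled null cohort shows only chance correlations", {
  sim <- generate_cohort(cohort_sim_config(beta_ts = 0, beta_cc = 0,
                                           mut_slope = 0, hazard_slope = 0,
                                           seed = 10))
  sums <- sum_family_expression(sim$cohort$mirna, sim$cohort$family_ids)
  prof <- correlate_genes(sums, sim$cohort$mrna)
  n <- ncol(sim$cohort$mrna)
  # null tail probability for |r| > 0.15 via the Fisher transform
  tail_p <- 2 * pnorm(-atanh(0.15) * sqrt(n - 3))
  frac <- mean(abs(prof$r) > 0.15)
  expect_lt(frac, tail_p + 4 * sqrt(tail_p / nrow(prof)))
})

test_that("cohort config rejects invalid settings", {
  expect_error(cohort_sim_config(n_tumors = 0), "positive")
  expect_error(cohort_sim_config(censor_rate = 1))
})
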