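test_that("normalize_counts rescales every library to one million", {
  m <- matrix(c(300, 200, 500), dimnames = list(c("a", "b", "c"), "s_rep1"))
  expect_equal(normalize_counts(m)[, 1],
               c(a = 3e5, b = 2e5, c = 5e5))

  # all-equal column of n vectors
  eq <- matrix(5, nrow = 8, ncol = 2,
               dimnames = list(letters[1:8], c("x_rep1", "x_rep2")))
  expect_true(all(normalize_counts(eq) == 1e6 / 8))

  # random table matches per-cell recomputation c * 1e6 / sum(c)
  set.seed(3)
  r <- matrix(rpois(40, 100), nrow = 10,
              dimnames = list(sprintf("v%d", 1:10), sprintf("s%d_rep1", 1:4)))
  norm <- normalize_counts(r)
  for (j in 1:4) {
    for (i in 1:10) {
      expect_equal(norm[i, j], r[i, j] * 1e6 / sum(r[, j]), tolerance = 1e-12)
    }
  }
  expect_equal(unname(colSums(norm)), rep(1e6, 4), tolerance = 1e-9 * 1e6)

  bad <- matrix(c(1, 2, 0, 0), nrow = 2,
                dimnames = list(c("a", "b"), c("ok_rep1", "dead_rep1")))
  expect_error(normalize_counts(bad), "dead_rep1")
})

test_that("read filter requires every replicate of one condition", {
  tab <- make_screen_table(
    Ctrl0 = rbind(c(310, 305, 400), c(299, 400, 400), c(500, 500, 500)),
    Ctrl30 = rbind(c(10, 20, 30), c(299, 400, 400), c(500, 500, 500)),
    Gef30 = rbind(c(0, 0, 0), c(299, 400, 400), c(500, 500, 500))
  )
  passed <- filter_min_reads(tab, threshold = 300)
  expect_true(passed["v1"])    # Ctrl0 qualifies on its own
  expect_false(passed["v2"])   # one replicate below threshold in every condition
  expect_true(passed["v3"])

  expect_true(all(filter_min_reads(tab, threshold = 0)))
  expect_error(filter_min_reads(tab, threshold = -1), "nonnegative")
})

test_that("raising the filter threshold never adds vectors", {
  sim <- generate_screen(screen_sim_config(n_vectors = 120, seed = 5))
  thresholds <- c(0, 50, 300, 1000, 5000)
  sets <- lapply(thresholds, function(th) {
    names(which(filter_min_reads(sim$table, threshold = th)))
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("enrichment_test handles identity, degenerate and Welch cases", {
  design <- parse_sample_design(c("A_rep1", "A_rep2", "A_rep3",
                                  "B_rep1", "B_rep2", "B_rep3"))
  # identical replicate values in both conditions
  norm <- matrix(1000, nrow = 1, ncol = 6,
                 dimnames = list("v1", design$sample))
  res <- enrichment_test(norm, design, "B", "A")
  expect_equal(res$log2_ratio, 0)
  expect_equal(res$p_value, 1)

  # zero variance, unequal means: log2 ratio 1 and limiting p = 0
  norm2 <- matrix(rep(c(2^10, 2^11), each = 3) - 0.5, nrow = 1,
                  dimnames = list("v1", design$sample))
  res2 <- enrichment_test(norm2, design, "B", "A", pseudocount = 0.5)
  expect_equal(res2$log2_ratio, 1)
  expect_equal(res2$p_value, 0)
  expect_true(res2$degenerate)

  # general case agrees with a direct Welch evaluation of the log2 values
  a <- c(9.1, 10.2, 9.7); b <- c(11.0, 11.8, 12.4)
  norm3 <- matrix(2^c(a, b) - 0.5, nrow = 1, dimnames = list("v1", design$sample))
  res3 <- enrichment_test(norm3, design, "B", "A", pseudocount = 0.5)
  expect_equal(res3$log2_ratio, mean(b) - mean(a), tolerance = 1e-10)
  expect_equal(res3$p_value, t.test(b, a)$p.value, tolerance = 1e-10)

  expect_error(enrichment_test(norm, design, "B", "nope"), "unknown condition")
})

test_that("hit classification applies the volcano cutoffs as stated", {
  cls <- classify_hits(c(2.0, 1.4, -1.6, 1.5, 0.2),
                       c(0.01, 0.001, 0.04, 0.05, 0.5))
  expect_equal(as.character(cls),
               c("enriched", "neutral", "depleted", "neutral", "neutral"))

  # partition is exhaustive and exclusive
  set.seed(2)
  lr <- rnorm(500, sd = 2); p <- runif(500)
  cls <- classify_hits(lr, p)
  expect_false(anyNA(cls))
  expect_equal(sum(table(cls)), 500)
  expect_true(all(lr[cls == "enriched"] >= 1.5 & p[cls == "enriched"] < 0.05))
  expect_true(all(lr[cls == "depleted"] <= -1.5 & p[cls == "depleted"] < 0.05))
  expect_error(classify_hits(1, 0.1, lfc_threshold = -1), "nonnegative")
})

test_that("hit intersection is order-stable and recovers the planted overlap", {
  expect_equal(intersect_hits(c("a", "b", "c"), c("b", "c", "d")), c("b", "c"))
  expect_equal(intersect_hits(c("x", "y"), character()), character())

  sim <- generate_screen(screen_sim_config(seed = 11))
  res <- screen_enrichment(sim$table)
  prolif <- res$vector_id[which(res$class_Ctrl30_vs_Ctrl0 == "enriched")]
  sensit <- res$vector_id[which(res$class_Gef30_vs_Ctrl30 == "depleted")]
  expect_setequal(intersect_hits(prolif, sensit), sim$truth$dual_ids)
})

test_that("proliferation index is (S + G2/M) / G0G1", {
  expect_equal(proliferation_index(50, 25, 25), 1.0)
  expect_equal(proliferation_index(80, 10, 10), 0.25)
  expect_equal(proliferation_index(40, 35, 25), 1.5)
  expect_error(proliferation_index(0, 50, 50), "positive")
})

test_that("delta-delta-Cq follows the ratio normalization convention", {
  same <- delta_delta_cq(c(20, 21), c(20, 21), reference_mean_dcq = 1)
  expect_equal(same$delta_cq, c(0, 0))

  ident <- delta_delta_cq(c(23, 23, 23), c(20, 20, 20), reference_mean_dcq = 3)
  expect_equal(ident$delta_delta_cq, 1)

  reps <- delta_delta_cq(c(25.1, 25.4), c(20.0, 20.1), reference_mean_dcq = 5.2)
  expect_equal(reps$delta_cq, c(5.1, 5.3))
  expect_equal(reps$mean_delta_cq, 5.2)
  expect_equal(reps$delta_delta_cq, 1)
  expect_error(delta_delta_cq(numeric(), numeric(), 1), "replicate")
})

test_that("screen_enrichment assembles filter, contrasts and classes", {
  sim <- generate_screen(screen_sim_config(n_vectors = 100, seed = 6))
  res <- screen_enrichment(sim$table)
  expect_equal(res$vector_id, rownames(sim$table$counts))
  expect_true(all(is.na(res$class_Ctrl30_vs_Ctrl0[!res$passed_filter])))
  expect_false(anyNA(res$class_Ctrl30_vs_Ctrl0[res$passed_filter]))
  expect_true(all(res$p_Ctrl30_vs_Ctrl0 >= 0 & res$p_Ctrl30_vs_Ctrl0 <= 1))
})
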