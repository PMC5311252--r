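test_that("summed family expression equals per-sample manual addition", {
  set.seed(8)
  m <- matrix(rexp(60), nrow = 6,
              dimnames = list(sprintf("mir%d", 1:6), sprintf("s%d", 1:10)))
  fam <- c("mir2", "mir3", "mir5", "mir1", "mir6")
  sums <- sum_family_expression(m, fam)
  for (j in 1:10) {
    expect_equal(unname(sums[j]), sum(m[fam, j]), tolerance = 1e-12)
  }
  # single-member family equals that row
  expect_equal(sum_family_expression(m, "mir4"), m["mir4", ])
  # all-zero members give zero
  m0 <- m; m0["mir1", ] <- 0; m0["mir2", ] <- 0
  expect_equal(unname(sum_family_expression(m0, c("mir1", "mir2"))),
               rep(0, 10))
  expect_warning(sum_family_expression(m, c("mir1", "ghost")), "ghost")
  expect_error(suppressWarnings(sum_family_expression(m, "ghost")),
               "no family member")
})

test_that("percentile groups use the ceiling rule and are ordered", {
  s100 <- setNames(rnorm(100), sprintf("s%03d", 1:100))
  g <- percentile_groups(s100, 5)
  expect_length(g$high, 5)
  expect_length(g$low, 5)

  s40 <- setNames(rnorm(40), sprintf("s%02d", 1:40))
  g40 <- percentile_groups(s40, 5)
  expect_length(g40$high, 2)

  expect_length(intersect(g$high, g$low), 0)
  expect_lte(max(s100[g$low]), min(s100[g$high]))
  expect_error(percentile_groups(setNames(rnorm(10), letters[1:10]), 5),
               "fewer than 2")
})

test_that("signature derivation selects planted genes and controls the null", {
  set.seed(12)
  n_genes <- 400
  expr <- matrix(rnorm(n_genes * 40, sd = 0.5), n_genes, 40,
                 dimnames = list(sprintf("g%03d", 1:n_genes),
                                 sprintf("s%02d", 1:40)))
  high <- sprintf("s%02d", 1:20); low <- sprintf("s%02d", 21:40)

  # permuted labels: no selections expected at FDR 1e-5
  null_sig <- derive_signature(expr, high, low)
  expect_lte(length(null_sig$genes), 1)

  # planted +3 shift with noise sd 0.5, groups of 20: far below threshold
  expr["g001", high] <- expr["g001", high] + 3
  sig <- derive_signature(expr, high, low)
  expect_true("g001" %in% sig$genes)
  expect_equal(sig$table$direction[sig$table$gene_id == "g001"], "up")

  # antisymmetry under group swap
  swapped <- derive_signature(expr, low, high)
  expect_equal(swapped$table$log2fc, -sig$table$log2fc, tolerance = 1e-12)
  expect_equal(swapped$table$p_value, sig$table$p_value, tolerance = 1e-12)

  expect_error(derive_signature(expr, high, c(high[1], low)), "disjoint")
})

test_that("two anti-correlated blocks cluster as blocks", {
  # block structure in the activity direction, shared baseline removed by
  # the default gene centering
  set.seed(14)
  genes <- 30
  base <- rnorm(genes)
  dir <- sample(c(-1, 1), genes, replace = TRUE)
  a <- c(rep(2, 6), rep(-2, 6)) + rnorm(12, sd = 0.1)
  expr <- outer(base, rep(1, 12)) + outer(dir, a) +
    matrix(rnorm(genes * 12, sd = 0.2), genes, 12)
  dimnames(expr) <- list(sprintf("g%d", 1:genes), sprintf("s%02d", 1:12))
  cl <- hierarchical_cluster(expr)
  expect_equal(length(unique(cl$clusters[1:6])), 1)
  expect_equal(length(unique(cl$clusters[7:12])), 1)
  expect_false(cl$clusters[1] == cl$clusters[7])
})

test_that("merge structure equals hand-computed complete linkage", {
  # 4 samples, 5 genes; oracle recomputes ranks, Spearman and the
  # agglomeration from the 6 pairwise distances by hand
  set.seed(15)
  expr <- matrix(rnorm(20), 5, 4,
                 dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:4)))
  cl <- hierarchical_cluster(expr, center_genes = FALSE)

  rho <- function(u, v) cor(rank(u), rank(v))   # Spearman via ranks
  d <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) d[i, j] <- 1 - rho(expr[, i], expr[, j])

  # manual complete-linkage agglomeration
  groups <- as.list(1:4)
  heights <- numeric(0)
  while (length(groups) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i < j) {
        dd <- max(d[groups[[i]], groups[[j]]])
        if (dd < best_d) { best_d <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups <- groups[-best[2]]
    if (length(groups) == 2) {
      # the k = 2 cut after this merge
      manual_k2 <- groups
    }
  }
  expect_equal(cl$sample_hclust$height, heights, tolerance = 1e-10)
  for (grp in manual_k2) {
    expect_equal(length(unique(cl$clusters[grp])), 1)
  }

  expect_error(
    hierarchical_cluster(matrix(c(1, 1, 1, 2, 3, 4), 3,
                                dimnames = list(NULL, c("flat", "ok")))),
    "flat")
})

test_that("rank-based clustering ignores per-sample monotone transforms", {
  set.seed(16)
  expr <- matrix(rnorm(200), 20, 10,
                 dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:10)))
  cl1 <- hierarchical_cluster(expr, center_genes = FALSE)
  warped <- expr
  for (j in 1:10) warped[, j] <- exp(expr[, j] / 2) * (j + 1)
  cl2 <- hierarchical_cluster(warped, center_genes = FALSE)
  expect_equal(cl1$clusters, cl2$clusters)
})

test_that("cluster labels follow mean family expression", {
  clusters <- setNames(c(1L, 1L, 2L, 2L), c("a", "b", "c", "d"))
  sums <- c(a = 10, b = 12, c = 100, d = 90)
  lab <- label_clusters(clusters, sums)
  expect_equal(as.character(lab[c("a", "c")]),
               c("cluster_low", "cluster_high"))
})

test_that("genotype association matches exact rank-sum enumeration", {
  res <- genotype_association(c(1, 2, 3, 4, 5, 6),
                              c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  # brute force over all C(6,3) = 20 labelings of the pooled sample
  vals <- 1:6
  combs <- combn(6, 3)
  W_obs <- sum(rank(vals)[1:3]) - 3 * 4 / 2
  W_all <- apply(combs, 2, function(ix) sum(rank(vals)[ix]) - 6)
  p_exact <- mean(abs(W_all - 4.5) >= abs(W_obs - 4.5))
  expect_equal(p_exact, 0.1)
  expect_equal(res$p_value, 0.1, tolerance = 1e-10)
  expect_true(res$exact)

  # identical group values: no shift in either direction
  tied <- genotype_association(rep(1, 6), rep(c(TRUE, FALSE), 3))
  expect_equal(tied$p_value, 1)

  # rank test invariant under monotone transform
  set.seed(19)
  x <- rnorm(30); g <- rep(c(TRUE, FALSE), 15)
  expect_equal(genotype_association(x, g)$p_value,
               genotype_association(exp(x), g)$p_value, tolerance = 1e-12)

  expect_error(genotype_association(1:5, rep(TRUE, 5)), "nonempty")
})
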