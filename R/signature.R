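#' Summed seed-family miRNA expression per sample
#'
#' Because family members share a target spectrum, their expression is
#' summed per sample (on the matrix's native scale, typically reads per
#' million). Family members missing from the matrix are skipped with a
#' warning.
#'
#' @param mirna_expr miRNA x sample matrix.
#' @param family a `seed_family` or character vector of miRNA ids.
#' @return named numeric vector of per-sample sums.
#' @export
sum_family_expression <- function(mirna_expr, family) {
  ids <- family_members(family)
  present <- ids %in% rownames(mirna_expr)
  if (any(!present)) {
    warning("family member(s) missing from the matrix: ",
            paste(ids[!present], collapse = ", "))
  }
  ids <- ids[present]
  if (length(ids) == 0L) stop("no family member present in the matrix")
  colSums(mirna_expr[ids, , drop = FALSE])
}

#' Top and bottom percentile sample groups
#'
#' Splits samples into the `k = ceiling(n * pct / 100)` lowest and highest
#' values of the summed family expression; ties are broken by sample id for
#' determinism.
#'
#' @param sums named numeric vector (e.g. from [sum_family_expression()]).
#' @param pct percentile (default 5).
#' @return list with character vectors `high` and `low` of sample ids.
#' @examples
#' s <- setNames(1:100, sprintf("s%03d", 1:100))
#' lengths(percentile_groups(s))
#' @export
percentile_groups <- function(sums, pct = 5) {
  n <- length(sums)
  if (is.null(names(sums))) stop("'sums' must be named by sample id")
  k <- ceiling(n * pct / 100)
  if (k < 2L) stop("percentile groups would have fewer than 2 samples")
  ord <- order(sums, names(sums))
  list(high = names(sums)[ord[(n - k + 1L):n]],
       low = names(sums)[ord[seq_len(k)]])
}

#' Derive a differential expression signature between sample groups
#'
#' Per-gene two-sided t-test (Welch by default) of the high vs low group on
#' log2 expression, with `log2fc = mean(high) - mean(low)`; p-values are
#' BH-adjusted over all tested genes and the signature keeps genes with
#' `FDR < fdr_threshold` and `|log2fc| > lfc_threshold`.
#'
#' @param mrna_expr gene x sample log2 expression matrix.
#' @param high,low disjoint character vectors of sample ids, each >= 2.
#' @param fdr_threshold FDR cutoff (default 1e-5).
#' @param lfc_threshold absolute log2 fold-change cutoff (default 1).
#' @param var_equal pooled-variance t instead of Welch.
#' @return object of class `signature_result`: list with `table` (data.frame
#'   `gene_id`, `log2fc`, `p_value`, `fdr`, `direction`, `selected`),
#'   `genes` (selected ids), `high`, `low`.
#' @export
derive_signature <- function(mrna_expr, high, low,
                             fdr_threshold = 1e-5, lfc_threshold = 1,
                             var_equal = FALSE) {
  if (length(intersect(high, low)) > 0L) stop("groups must be disjoint")
  if (length(high) < 2L || length(low) < 2L) {
    stop("each group needs at least 2 samples")
  }
  missing <- setdiff(c(high, low), colnames(mrna_expr))
  if (length(missing) > 0L) {
    stop("sample(s) absent from the matrix: ", paste(missing, collapse = ", "))
  }
  tt <- row_t_test(mrna_expr[, high, drop = FALSE],
                   mrna_expr[, low, drop = FALSE], var_equal = var_equal)
  fdr <- bh_adjust(tt$p_value)
  selected <- fdr < fdr_threshold & abs(tt$estimate) > lfc_threshold
  tab <- data.frame(
    gene_id = rownames(mrna_expr),
    log2fc = tt$estimate,
    p_value = tt$p_value,
    fdr = fdr,
    direction = ifelse(tt$estimate > 0, "up", "down"),
    selected = selected,
    row.names = NULL
  )
  structure(list(table = tab, genes = tab$gene_id[selected],
                 high = high, low = low),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("signature_result: %d / %d genes selected (%d up, %d down)\n",
              length(x$genes), nrow(x$table),
              sum(x$table$selected & x$table$direction == "up"),
              sum(x$table$selected & x$table$direction == "down")))
  invisible(x)
}

#' Hierarchical clustering of samples on signature genes
#'
#' Pairwise sample distance `1 - Spearman correlation` over the signature
#' genes, agglomerated with complete linkage; the two main clusters are the
#' k = 2 cut of the final merge. Genes are clustered the same way (for
#' heat-map ordering). By default each gene is mean-centered first
#' (heat-map convention): without centering, the shared per-gene baseline
#' dominates every pairwise correlation and the k = 2 cut degenerates to an
#' unstable diameter split instead of the two main expression groups. With
#' `center_genes = FALSE` the distance is rank-based per sample, making
#' cluster labels invariant under strictly increasing per-sample
#' transforms. Ties in merge heights resolve by `stats::hclust`'s index
#' order.
#'
#' @param mrna_expr gene x sample expression matrix.
#' @param genes signature gene ids to restrict to (default: all rows).
#' @param k number of main clusters (default 2).
#' @param center_genes subtract each gene's mean across samples before
#'   computing sample-sample correlations (default TRUE).
#' @return list with `clusters` (named integer vector of cluster ids),
#'   `sample_hclust`, `gene_hclust`.
#' @export
hierarchical_cluster <- function(mrna_expr, genes = NULL, k = 2L,
                                 center_genes = TRUE) {
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(mrna_expr))
    if (length(missing) > 0L) {
      stop("gene(s) absent from the matrix: ",
           paste(missing, collapse = ", "))
    }
    mrna_expr <- mrna_expr[genes, , drop = FALSE]
  }
  if (nrow(mrna_expr) < 2L || ncol(mrna_expr) < 2L) {
    stop("need at least 2 genes and 2 samples")
  }
  const <- apply(mrna_expr, 2L, function(v) length(unique(v)) == 1L)
  if (any(const)) {
    stop("constant expression profile for sample(s): ",
         paste(colnames(mrna_expr)[const], collapse = ", "))
  }
  work <- if (center_genes) mrna_expr - rowMeans(mrna_expr) else mrna_expr
  d_samp <- stats::as.dist(1 - stats::cor(work, method = "spearman"))
  hc_samp <- stats::hclust(d_samp, method = "complete")
  clusters <- stats::cutree(hc_samp, k = k)

  gene_const <- apply(mrna_expr, 1L, function(v) length(unique(v)) == 1L)
  hc_gene <- if (sum(!gene_const) >= 2L) {
    stats::hclust(stats::as.dist(
      1 - stats::cor(t(work[!gene_const, , drop = FALSE]),
                     method = "spearman")), method = "complete")
  } else NULL

  list(clusters = clusters, sample_hclust = hc_samp, gene_hclust = hc_gene)
}

#' Label the two main clusters by family expression
#'
#' Names the cluster whose samples have the larger mean summed family
#' expression `cluster_high`, the other `cluster_low`.
#'
#' @param clusters named integer cluster ids (from
#'   [hierarchical_cluster()] with k = 2).
#' @param sums named per-sample summed family expression.
#' @return named factor with levels `cluster_high`, `cluster_low`.
#' @export
label_clusters <- function(clusters, sums) {
  stopifnot(length(unique(clusters)) == 2L)
  m <- tapply(sums[names(clusters)], clusters, mean)
  high_id <- as.integer(names(m)[which.max(m)])
  factor(ifelse(clusters == high_id, "cluster_high", "cluster_low"),
         levels = c("cluster_high", "cluster_low"))
}

#' Genotype association of family expression
#'
#' Two-sided Wilcoxon rank-sum test of the summed family expression between
#' two genotype groups (e.g. TP53-mutant vs wild type). Exact enumeration is
#' used for combined n <= 20 without ties; otherwise the normal
#' approximation with tie correction.
#'
#' @param sums numeric vector of per-sample values.
#' @param binary_label logical or 0/1 vector of the same length.
#' @return list with `statistic` (rank-sum W), `p_value`, `exact`.
#' @export
genotype_association <- function(sums, binary_label) {
  g <- as.logical(binary_label)
  if (anyNA(g) || length(unique(g)) < 2L) {
    stop("both label groups must be nonempty")
  }
  x <- sums[g]
  y <- sums[!g]
  if (length(unique(c(x, y))) == 1L) {
    # all observations tied: no evidence of a shift in either direction
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                exact = TRUE))
  }
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y)) <= 20L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = !exact)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}
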