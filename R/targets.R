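#' Differential table for a mimic-vs-control arm pair
#'
#' Per-gene log2 fold change and two-sided t-test p-value between a case
#' (mimic-transfected) and control matrix of log2-scale abundances.
#' `log2fc = mean(case) - mean(control)`; the t-test variant and
#' zero-variance limit rules are those of [row_t_test()].
#'
#' @param case_matrix,control_matrix log2 abundance matrices, genes in rows
#'   (same gene universe), >= 2 replicate columns each.
#' @param var_equal pooled-variance t instead of Welch.
#' @return data.frame with `gene_id`, `log2fc`, `p_value`, `degenerate`.
#' @export
differential_table <- function(case_matrix, control_matrix,
                               var_equal = FALSE) {
  if (is.null(dim(case_matrix))) case_matrix <- t(as.matrix(case_matrix))
  if (is.null(dim(control_matrix))) control_matrix <- t(as.matrix(control_matrix))
  if (!identical(rownames(case_matrix), rownames(control_matrix))) {
    if (is.null(rownames(case_matrix)) ||
        !setequal(rownames(case_matrix), rownames(control_matrix))) {
      stop("case and control matrices must share one gene universe")
    }
    control_matrix <- control_matrix[rownames(case_matrix), , drop = FALSE]
  }
  tt <- row_t_test(case_matrix, control_matrix, var_equal = var_equal)
  data.frame(
    gene_id = if (is.null(rownames(case_matrix)))
      as.character(seq_len(nrow(case_matrix))) else rownames(case_matrix),
    log2fc = tt$estimate,
    p_value = tt$p_value,
    degenerate = tt$degenerate,
    row.names = NULL
  )
}

#' Stratify genes by prediction-algorithm consensus
#'
#' Bins the number of target-prediction algorithms nominating each gene into
#' the four consensus strata `"0"`, `"1-2"`, `"3-4"` and `">4"` (counts of 5
#' and above fall in `">4"`).
#'
#' @param prediction_count integer vector of per-gene counts in
#'   `0..n_algorithms`.
#' @param n_algorithms maximum possible count (default 9).
#' @return factor with levels `"0"`, `"1-2"`, `"3-4"`, `">4"`.
#' @examples
#' stratify_by_predictions(c(0, 2, 4, 5, 9))
#' @export
stratify_by_predictions <- function(prediction_count, n_algorithms = 9L) {
  if (any(is.na(prediction_count)) ||
      any(prediction_count < 0 | prediction_count > n_algorithms) ||
      any(prediction_count != round(prediction_count))) {
    stop("prediction counts must be integers in 0..", n_algorithms)
  }
  cut(prediction_count, breaks = c(-0.5, 0.5, 2.5, 4.5, n_algorithms + 0.5),
      labels = c("0", "1-2", "3-4", ">4"))
}

#' ECDF shift of fold changes across prediction strata
#'
#' Builds a right-continuous empirical cumulative distribution of fold
#' changes per stratum and quantifies the shift of each stratum against a
#' reference stratum with a two-sample Kolmogorov-Smirnov test
#' (asymptotic p-values). A leftward shift of high-consensus strata
#' evidences genuine target repression.
#'
#' @param fold_changes numeric vector (e.g. `log2fc` per gene).
#' @param strata factor of the same length (e.g. from
#'   [stratify_by_predictions()]).
#' @param reference reference stratum label (default `"0"`).
#' @return list with `curves` (named list of data.frames `x`, `F`) and
#'   `tests` (data.frame `stratum`, `n`, `ks_statistic`, `p_value`).
#' @export
ecdf_shift <- function(fold_changes, strata, reference = "0") {
  strata <- as.factor(strata)
  ref_x <- fold_changes[strata == reference]
  if (length(ref_x) == 0L) stop("reference stratum is empty")

  curves <- list()
  tests <- list()
  for (lev in levels(strata)) {
    x <- fold_changes[strata == lev]
    if (length(x) == 0L) {
      warning("stratum '", lev, "' is empty; curve omitted")
      next
    }
    xs <- sort(x)
    curves[[lev]] <- data.frame(x = xs, F = seq_along(xs) / length(xs))
    if (lev != reference) {
      ks <- suppressWarnings(
        stats::ks.test(x, ref_x, exact = FALSE)
      )
      tests[[lev]] <- data.frame(stratum = lev, n = length(x),
                                 ks_statistic = unname(ks$statistic),
                                 p_value = ks$p.value)
    }
  }
  list(curves = curves,
       tests = do.call(rbind, c(tests, list(make.row.names = FALSE))))
}

#' Build a per-gene evidence table
#'
#' Joins the mRNA differential table, the (optional) protein differential
#' table and the prediction-count table into one table over the mRNA gene
#' universe. Genes missing from the protein layer keep NA protein columns
#' and are evaluable via the mRNA branch only; missingness is recorded,
#' never imputed.
#'
#' @param mrna_diff data.frame from [differential_table()] (mRNA layer).
#' @param protein_diff same for the protein layer, or `NULL` when the
#'   protein layer is unavailable (a warning notes the degradation).
#' @param predictions data.frame with `gene_id`, `prediction_count`.
#' @param n_algorithms forwarded to [stratify_by_predictions()].
#' @return data.frame with columns `gene_id`, `mrna_log2fc`, `mrna_p`,
#'   `protein_log2fc`, `protein_p`, `prediction_count`, `stratum`.
#' @export
build_evidence_table <- function(mrna_diff, protein_diff, predictions,
                                 n_algorithms = 9L) {
  out <- data.frame(
    gene_id = mrna_diff$gene_id,
    mrna_log2fc = mrna_diff$log2fc,
    mrna_p = mrna_diff$p_value
  )
  if (is.null(protein_diff)) {
    warning("no protein layer supplied; evidence degrades to mRNA only")
    out$protein_log2fc <- NA_real_
    out$protein_p <- NA_real_
  } else {
    i <- match(out$gene_id, protein_diff$gene_id)
    out$protein_log2fc <- protein_diff$log2fc[i]
    out$protein_p <- protein_diff$p_value[i]
  }
  j <- match(out$gene_id, predictions$gene_id)
  if (anyNA(j)) stop("prediction counts missing for some genes")
  out$prediction_count <- predictions$prediction_count[j]
  out$stratum <- stratify_by_predictions(out$prediction_count, n_algorithms)
  out
}

#' Call putative miRNA targets from multi-layer evidence
#'
#' A gene is a putative target iff it is significantly downregulated at the
#' mRNA and/or protein level (log2fc < 0 and p < `p_threshold` on either
#' layer) AND nominated by at least `min_predictions` prediction algorithms.
#' The `evidence` column records which branch(es) fired.
#'
#' @param evidence data.frame from [build_evidence_table()].
#' @param p_threshold significance cutoff per layer (default 0.05).
#' @param min_predictions consensus cutoff (default 5, i.e. "more than
#'   four algorithms").
#' @return the evidence table augmented with `evidence`
#'   (`mRNA`/`protein`/`both`/`none`) and logical `putative_target`.
#' @examples
#' ev <- data.frame(gene_id = "g1", mrna_log2fc = -0.8, mrna_p = 0.01,
#'                  protein_log2fc = NA, protein_p = NA, prediction_count = 5)
#' call_putative_targets(ev)$putative_target
#' @export
call_putative_targets <- function(evidence, p_threshold = 0.05,
                                  min_predictions = 5L) {
  mr <- !is.na(evidence$mrna_p) &
    evidence$mrna_log2fc < 0 & evidence$mrna_p < p_threshold
  pr <- !is.na(evidence$protein_p) &
    evidence$protein_log2fc < 0 & evidence$protein_p < p_threshold
  lab <- rep("none", nrow(evidence))
  lab[mr & !pr] <- "mRNA"
  lab[pr & !mr] <- "protein"
  lab[mr & pr] <- "both"
  evidence$evidence <- factor(lab, levels = c("mRNA", "protein", "both", "none"))
  evidence$putative_target <- (mr | pr) &
    evidence$prediction_count >= min_predictions
  evidence
}

#' Histogram of prediction counts
#'
#' Exact counts of genes per consensus value `0..n_algorithms`; no smoothing.
#' (The empirical distribution is typically bimodal, motivating the
#' five-algorithm consensus cutoff.)
#'
#' @param prediction_count integer vector of per-gene counts.
#' @param n_algorithms maximum possible count (default 9).
#' @return named integer vector over `0:n_algorithms`.
#' @export
prediction_count_histogram <- function(prediction_count, n_algorithms = 9L) {
  if (any(prediction_count < 0 | prediction_count > n_algorithms)) {
    stop("prediction counts must lie in 0..", n_algorithms)
  }
  stats::setNames(
    tabulate(prediction_count + 1L, nbins = n_algorithms + 1L),
    0:n_algorithms
  )
}
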