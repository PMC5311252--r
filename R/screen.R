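#' Normalize screen counts to reads per million
#'
#' Scales every sequencing library to total reads: each entry becomes
#' `count / column total * 1e6`, so column sums equal one million.
#'
#' @param table a [screen_count_table()] or a nonnegative count matrix.
#' @return real-valued matrix of the same shape, in reads per million.
#' @examples
#' normalize_counts(matrix(c(300, 200, 500), dimnames = list(letters[1:3], "s_rep1")))
#' @export
normalize_counts <- function(table) {
  counts <- if (inherits(table, "screen_count_table")) table$counts else as.matrix(table)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("zero-total sample(s): ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  }
  sweep(counts, 2L, totals, `/`) * 1e6
}

#' Minimum-read filter for screen vectors
#'
#' A vector is retained iff there exists a condition in which every
#' replicate's raw count reaches the threshold (the filter operates on raw
#' counts, before normalization).
#'
#' @param table a [screen_count_table()].
#' @param threshold minimum raw read count (default 300).
#' @return named logical vector, `TRUE` for retained vectors.
#' @examples
#' sim <- generate_screen(screen_sim_config(n_vectors = 50, seed = 1))
#' sum(filter_min_reads(sim$table))
#' @export
filter_min_reads <- function(table, threshold = 300) {
  stopifnot(inherits(table, "screen_count_table"))
  if (threshold < 0) stop("'threshold' must be nonnegative")
  conds <- unique(table$design$condition)
  per_cond <- vapply(conds, function(cond) {
    cols <- table$design$sample[table$design$condition == cond]
    rowSums(table$counts[, cols, drop = FALSE] >= threshold) == length(cols)
  }, logical(nrow(table$counts)))
  passed <- rowSums(per_cond) > 0
  names(passed) <- rownames(table$counts)
  passed
}

#' Enrichment/depletion test for one screen contrast
#'
#' Per vector, replicate values `x = log2(RPM + pseudocount)` are compared
#' between two conditions with a two-sided two-sample t-test (Welch by
#' default). The log2 ratio is `mean(x[numerator]) - mean(x[denominator])`.
#' Rows with zero variance in both groups take the analytic limit
#' (p = 1 for equal means, p = 0 otherwise) and are flagged.
#'
#' @param norm normalized (RPM) matrix from [normalize_counts()].
#' @param design sample design data.frame (`sample`, `condition`,
#'   `replicate`).
#' @param numerator,denominator condition labels of the contrast
#'   (`numerator/denominator` on the fold scale).
#' @param pseudocount added before the log2 transform (default 0.5).
#' @param var_equal use Student's pooled-variance t instead of Welch.
#' @return data.frame with columns `vector_id`, `log2_ratio`, `statistic`,
#'   `p_value`, `degenerate`.
#' @export
enrichment_test <- function(norm, design, numerator, denominator,
                            pseudocount = 0.5, var_equal = FALSE) {
  for (cond in c(numerator, denominator)) {
    if (!cond %in% design$condition) {
      stop("unknown condition label: ", cond)
    }
    if (sum(design$condition == cond) < 2L) {
      stop("condition ", cond, " has fewer than 2 replicates")
    }
  }
  x <- log2(norm + pseudocount)
  num_cols <- design$sample[design$condition == numerator]
  den_cols <- design$sample[design$condition == denominator]
  tt <- row_t_test(x[, num_cols, drop = FALSE], x[, den_cols, drop = FALSE],
                   var_equal = var_equal)
  data.frame(
    vector_id = rownames(norm),
    log2_ratio = tt$estimate,
    statistic = tt$statistic,
    p_value = tt$p_value,
    degenerate = tt$degenerate,
    row.names = NULL
  )
}

#' Classify screen vectors into enriched / depleted / neutral
#'
#' Applies the volcano cutoffs: enriched iff `log2_ratio >= lfc_threshold`
#' and `p < p_threshold`; depleted iff `log2_ratio <= -lfc_threshold` and
#' `p < p_threshold`; neutral otherwise. Fold thresholds are inclusive, the
#' p threshold strict.
#'
#' @param log2_ratio,p_value numeric vectors (typically from
#'   [enrichment_test()]).
#' @param lfc_threshold log2 fold-change cutoff (default 1.5).
#' @param p_threshold p-value cutoff (default 0.05).
#' @return factor with levels `enriched`, `depleted`, `neutral`.
#' @examples
#' classify_hits(c(2, 1.4, -1.6), c(0.01, 0.001, 0.04))
#' @export
classify_hits <- function(log2_ratio, p_value,
                          lfc_threshold = 1.5, p_threshold = 0.05) {
  if (lfc_threshold < 0 || p_threshold < 0) {
    stop("thresholds must be nonnegative")
  }
  cls <- rep("neutral", length(log2_ratio))
  cls[log2_ratio >= lfc_threshold & p_value < p_threshold] <- "enriched"
  cls[log2_ratio <= -lfc_threshold & p_value < p_threshold] <- "depleted"
  factor(cls, levels = c("enriched", "depleted", "neutral"))
}

#' Intersect proliferation and sensitization hit sets
#'
#' Returns the vectors called in both screens (e.g. enriched after long-term
#' culture and depleted under drug), in the stable order of the first set.
#'
#' @param proliferation_hits,sensitization_hits character vectors of ids.
#' @return character vector of shared ids.
#' @export
intersect_hits <- function(proliferation_hits, sensitization_hits) {
  proliferation_hits[proliferation_hits %in% sensitization_hits]
}

#' Full screen enrichment/depletion analysis
#'
#' Orchestrates normalization, the minimum-read filter, the configured
#' contrasts and hit classification into one result table (one row per
#' vector; per-contrast columns suffixed with `numerator_vs_denominator`).
#' Classes are only assigned to vectors passing the filter.
#'
#' @param table a [screen_count_table()].
#' @param contrasts list of `c(numerator, denominator)` pairs; default:
#'   consecutive condition pairs (second vs first, third vs second, ...).
#' @param min_reads raw-read filter threshold.
#' @param pseudocount,var_equal passed to [enrichment_test()].
#' @param lfc_threshold,p_threshold passed to [classify_hits()].
#' @return data.frame with `vector_id`, `passed_filter`, per-condition mean
#'   log2 RPM columns and per-contrast `log2_ratio_*`, `p_*`, `class_*`
#'   columns (class is NA for filtered-out vectors).
#' @examples
#' sim <- generate_screen(screen_sim_config(n_vectors = 80, seed = 2))
#' res <- screen_enrichment(sim$table)
#' table(res$class_Ctrl30_vs_Ctrl0)
#' @export
screen_enrichment <- function(table, contrasts = NULL, min_reads = 300,
                              pseudocount = 0.5, var_equal = FALSE,
                              lfc_threshold = 1.5, p_threshold = 0.05) {
  stopifnot(inherits(table, "screen_count_table"))
  conds <- unique(table$design$condition)
  if (is.null(contrasts)) {
    contrasts <- lapply(seq_len(length(conds) - 1L),
                        function(i) c(conds[i + 1L], conds[i]))
  }
  norm <- normalize_counts(table)
  passed <- filter_min_reads(table, threshold = min_reads)

  out <- data.frame(vector_id = rownames(table$counts),
                    passed_filter = unname(passed))
  x <- log2(norm + pseudocount)
  for (cond in conds) {
    cols <- table$design$sample[table$design$condition == cond]
    out[[paste0("mean_log2rpm_", cond)]] <-
      rowMeans(x[, cols, drop = FALSE])
  }
  for (ct in contrasts) {
    tag <- paste0(ct[1], "_vs_", ct[2])
    et <- enrichment_test(norm, table$design, ct[1], ct[2],
                          pseudocount = pseudocount, var_equal = var_equal)
    cls <- classify_hits(et$log2_ratio, et$p_value,
                         lfc_threshold = lfc_threshold,
                         p_threshold = p_threshold)
    cls[!passed] <- NA
    out[[paste0("log2_ratio_", tag)]] <- et$log2_ratio
    out[[paste0("p_", tag)]] <- et$p_value
    out[[paste0("class_", tag)]] <- cls
  }
  out
}

#' Proliferation index from cell-cycle phase fractions
#'
#' The ratio between cycling (S plus G2/M) and resting (G0/G1) cells.
#'
#' @param g0g1,s,g2m phase percentages or fractions (same scale).
#' @return `(s + g2m) / g0g1`, vectorized.
#' @examples
#' proliferation_index(50, 25, 25)
#' @export
proliferation_index <- function(g0g1, s, g2m) {
  if (any(g0g1 < 0 | s < 0 | g2m < 0)) {
    stop("phase values must be nonnegative")
  }
  if (any(g0g1 == 0)) stop("G0/G1 fraction must be positive")
  (s + g2m) / g0g1
}

#' Relative qPCR quantification (delta-delta-Cq)
#'
#' Per replicate, the target quantitation cycle is normalized to the
#' reference small RNA (`dCq = Cq_target - Cq_reference`); the replicate mean
#' dCq is then normalized to the control condition's mean dCq by ratio.
#'
#' @param cq_target,cq_reference per-replicate quantitation cycles.
#' @param reference_mean_dcq mean dCq of the non-targeting control.
#' @return list with `delta_cq` (per replicate), `mean_delta_cq` and
#'   `delta_delta_cq`.
#' @examples
#' delta_delta_cq(c(25.1, 25.4), c(20.0, 20.1), reference_mean_dcq = 5.2)
#' @export
delta_delta_cq <- function(cq_target, cq_reference, reference_mean_dcq) {
  if (length(cq_target) == 0L) stop("at least one replicate required")
  if (length(cq_target) != length(cq_reference)) {
    stop("target and reference Cq vectors must align")
  }
  if (any(!is.finite(cq_target)) || any(!is.finite(cq_reference))) {
    stop("Cq values must be finite")
  }
  dcq <- cq_target - cq_reference
  list(
    delta_cq = dcq,
    mean_delta_cq = mean(dcq),
    delta_delta_cq = mean(dcq) / reference_mean_dcq
  )
}
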