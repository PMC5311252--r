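#' Per-gene correlation with summed family expression
#'
#' Pearson correlation between each gene's expression and the per-sample
#' summed family expression, on `log2(sum + 1)` by default (set
#' `log_transform = FALSE` for the native scale). Genes with zero variance
#' get NA correlation (flagged via `defined`), never r = 0.
#'
#' @param sums named per-sample summed family expression (see
#'   [sum_family_expression()]).
#' @param mrna_expr gene x sample expression matrix (same samples).
#' @param log_transform correlate against `log2(sum + 1)` (default TRUE).
#' @param annotation optional data.frame `gene_id`, `role` merged into the
#'   profile (e.g. TS panel / transcription factor / host gene / cell cycle).
#' @return data.frame with `gene_id`, `r`, `n`, `defined` and optionally
#'   `role`.
#' @export
correlate_genes <- function(sums, mrna_expr, log_transform = TRUE,
                            annotation = NULL) {
  if (!setequal(names(sums), colnames(mrna_expr))) {
    stop("samples of 'sums' and 'mrna_expr' must match")
  }
  if (length(sums) < 3L) stop("need at least 3 samples")
  x <- sums[colnames(mrna_expr)]
  if (log_transform) x <- log2(x + 1)
  gene_sd <- apply(mrna_expr, 1L, stats::sd)
  r <- suppressWarnings(as.vector(stats::cor(x, t(mrna_expr))))
  r[gene_sd == 0] <- NA_real_
  out <- data.frame(
    gene_id = rownames(mrna_expr),
    r = r,
    n = length(x),
    defined = gene_sd > 0,
    row.names = NULL
  )
  if (!is.null(annotation)) {
    out$role <- annotation$role[match(out$gene_id, annotation$gene_id)]
  }
  out
}

#' Call inversely correlated targets
#'
#' Genes of the candidate set whose correlation with summed family
#' expression falls strictly below the threshold (default -0.15); these are
#' the candidate targets whose repression is visible at cohort level.
#'
#' @param profile data.frame from [correlate_genes()].
#' @param threshold correlation cutoff, strict `<` (default -0.15).
#' @param candidate_set gene ids to consider (subset of the profile);
#'   default: all profiled genes.
#' @return character vector of called gene ids.
#' @export
call_inverse_targets <- function(profile, threshold = -0.15,
                                 candidate_set = NULL) {
  if (is.null(candidate_set)) candidate_set <- profile$gene_id
  missing <- setdiff(candidate_set, profile$gene_id)
  if (length(missing) > 0L) {
    stop("candidate(s) absent from the profile: ",
         paste(missing, collapse = ", "))
  }
  sub <- profile[profile$gene_id %in% candidate_set, , drop = FALSE]
  sub$gene_id[!is.na(sub$r) & sub$r < threshold]
}

#' ECDF of per-gene correlations
#'
#' Empirical cumulative distribution over the defined correlations of a
#' profile; the number of undefined (zero-variance) genes is attached as the
#' `n_undefined` attribute.
#'
#' @param profile data.frame from [correlate_genes()].
#' @return an [stats::ecdf()] step function.
#' @export
correlation_ecdf <- function(profile) {
  r <- profile$r[!is.na(profile$r)]
  if (length(r) == 0L) stop("no defined correlations")
  f <- stats::ecdf(r)
  attr(f, "n_undefined") <- sum(is.na(profile$r))
  f
}

#' Rank cancer types by tumor-suppressor panel correlation
#'
#' Per cancer type, the mean correlation over the TS-panel genes; cancers
#' are ordered from the strongest average negative correlation upward, ties
#' broken by label. Panel genes missing from a profile are dropped with a
#' warning.
#'
#' @param profiles named list of [correlate_genes()] data.frames, one per
#'   cancer type.
#' @param ts_panel character vector of panel gene ids.
#' @return data.frame with `cancer`, `mean_ts_r`, `n_genes`, sorted
#'   ascending by `mean_ts_r`.
#' @export
rank_cancers_by_ts_correlation <- function(profiles, ts_panel) {
  rows <- lapply(names(profiles), function(cn) {
    prof <- profiles[[cn]]
    present <- ts_panel %in% prof$gene_id
    if (any(!present)) {
      warning("cancer ", cn, ": panel gene(s) dropped: ",
              paste(ts_panel[!present], collapse = ", "))
    }
    genes <- ts_panel[present]
    if (length(genes) == 0L) stop("cancer ", cn, ": empty panel")
    r <- prof$r[match(genes, prof$gene_id)]
    data.frame(cancer = cn, mean_ts_r = mean(r, na.rm = TRUE),
               n_genes = length(genes))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mean_ts_r, out$cancer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a correlation-colored network
#'
#' Produces a deterministic node table (gene, role, r, color bin) from a
#' curated node file and the correlation profile, plus an edge list copied
#' verbatim from the curation — edges are never inferred; the module is a
#' correlation profiler, not a structure learner. Default bin edges are
#' symmetric at +/-0.15 and +/-0.4.
#'
#' @param profile data.frame from [correlate_genes()].
#' @param nodes data.frame with columns `gene_id`, `role`.
#' @param edges optional data.frame with columns `from`, `to`, `relation`;
#'   copied to the output unchanged.
#' @param bin_edges increasing numeric vector of interior bin boundaries.
#' @return list with `nodes` (data.frame `gene_id`, `role`, `r`,
#'   `color_bin`) and `edges`.
#' @export
export_network <- function(profile, nodes, edges = NULL,
                           bin_edges = c(-0.4, -0.15, 0.15, 0.4)) {
  stopifnot(!is.unsorted(bin_edges))
  r <- profile$r[match(nodes$gene_id, profile$gene_id)]
  absent <- !nodes$gene_id %in% profile$gene_id
  if (any(absent)) {
    warning("curated node(s) absent from the profile: ",
            paste(nodes$gene_id[absent], collapse = ", "))
  }
  breaks <- c(-Inf, bin_edges, Inf)
  labels <- character(length(breaks) - 1L)
  for (i in seq_along(labels)) {
    labels[i] <- sprintf("(%s,%s]", breaks[i], breaks[i + 1L])
  }
  out_nodes <- data.frame(
    gene_id = nodes$gene_id,
    role = nodes$role,
    r = r,
    color_bin = cut(r, breaks = breaks, labels = labels)
  )
  list(nodes = out_nodes, edges = edges)
}

#' Median summed family expression (RPM) of a cohort
#'
#' The per-cohort median over samples of the summed family expression, on
#' the native reads-per-million scale — the single-number summary used to
#' compare family expression across cancer types.
#'
#' @param mirna_expr miRNA x sample RPM matrix.
#' @param family a `seed_family` or character vector of miRNA ids.
#' @return median of per-sample sums.
#' @export
median_family_rpm <- function(mirna_expr, family) {
  stats::median(sum_family_expression(mirna_expr, family))
}
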