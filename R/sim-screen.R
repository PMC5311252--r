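# Random RNA sequence helpers used by the screen generator. Background seeds
# are rejection-sampled so that only planted hits carry the motif within the
# seed region; this guarantees motif specificity of the planted truth.

.rna_alphabet <- c("A", "C", "G", "U")

.random_rna <- function(len) {
  paste(sample(.rna_alphabet, len, replace = TRUE), collapse = "")
}

.random_seq_without_motif <- function(len, motif, seed_len = 8L) {
  repeat {
    s <- .random_rna(len)
    if (!grepl(motif, substr(s, 1L, seed_len), fixed = TRUE)) {
      return(s)
    }
  }
}

.random_seq_with_motif <- function(len, motif, seed_len = 8L) {
  k <- nchar(motif)
  offset <- sample.int(seed_len - k + 1L, 1L) - 1L
  s <- strsplit(.random_rna(len), "", fixed = TRUE)[[1]]
  s[(offset + 1L):(offset + k)] <- strsplit(motif, "", fixed = TRUE)[[1]]
  paste(s, collapse = "")
}

#' Assemble a screen count table
#'
#' Bundles a nonnegative integer count matrix (miR-Vec clones in rows,
#' sequencing libraries in columns) with the sample design mapping each column
#' to a condition and replicate, validating the contract the screen statistics
#' rely on.
#'
#' @param counts integer matrix; row names are vector ids, column names are
#'   sample names.
#' @param design data.frame with columns `sample`, `condition`, `replicate`;
#'   if omitted it is parsed from column names of the form `Condition_rep#`.
#' @return object of class `screen_count_table` (a list with elements
#'   `counts` and `design`).
#' @export
screen_count_table <- function(counts, design = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop("count rows must carry unique vector ids")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (is.null(design)) {
    design <- parse_sample_design(colnames(counts))
  }
  design$sample <- as.character(design$sample)
  design$condition <- as.character(design$condition)
  if (!setequal(design$sample, colnames(counts)) ||
      anyDuplicated(design$sample)) {
    stop("design samples must match count columns exactly")
  }
  design <- design[match(colnames(counts), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  if (any(table(design$condition) < 2L)) {
    stop("each condition needs at least 2 replicates")
  }
  structure(list(counts = counts, design = design),
            class = "screen_count_table")
}

#' Parse a sample design from `Condition_rep#` column names
#'
#' @param samples character vector of sample names.
#' @return data.frame with columns `sample`, `condition`, `replicate`.
#' @export
parse_sample_design <- function(samples) {
  m <- regmatches(samples, regexec("^(.+)_rep([0-9]+)$", samples))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("cannot parse condition/replicate from sample name(s): ",
         paste(samples[bad], collapse = ", "))
  }
  data.frame(
    sample = samples,
    condition = vapply(m, `[`, "", 2L),
    replicate = as.integer(vapply(m, `[`, "", 3L))
  )
}

#' @export
print.screen_count_table <- function(x, ...) {
  cat(sprintf("screen_count_table: %d vectors x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$design$condition), collapse = ", ")))
  invisible(x)
}

#' Simulate a pooled miR-Vec overexpression screen
#'
#' Draws negative-binomial read counts for a library of miRNA expression
#' vectors across the configured conditions. Baseline clone abundances are
#' log-normal; planted enriched clones gain `2^log2_effect_enrich` in relative
#' abundance between the first and second condition, and planted depleted
#' (drug-sensitized) clones lose `2^log2_effect_deplete` between the second
#' and third. Per condition, relative abundances are renormalized (a pooled
#' screen measures composition) and counts drawn with mean
#' `depth * relative abundance` and variance `mu + dispersion * mu^2`.
#' Planted hit miRNAs carry the configured motif within seed positions 1-8;
#' background seeds are motif-free by rejection sampling.
#'
#' @param cfg a [screen_sim_config()].
#' @return list with elements `table` (a [screen_count_table()]), `catalogue`
#'   (data.frame of `mirna_id`, `sequence`), and `truth` (list with
#'   `enriched_ids`, `depleted_ids`, `dual_ids`, `motif`, `expected_mu`
#'   — the per-replicate expected count of each vector in each condition —
#'   and `seed_used`).
#' @examples
#' sim <- generate_screen(screen_sim_config(n_vectors = 60, seed = 1))
#' dim(sim$table$counts)
#' @export
generate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_vectors
    ids <- sprintf("syn-mir-%04d", seq_len(n))

    w <- stats::rlnorm(n, meanlog = 0, sdlog = cfg$abundance_sdlog)
    mu0 <- cfg$depth * w / sum(w)

    n_hits <- cfg$n_enriched + cfg$n_depleted - cfg$n_dual
    eligible <- which(mu0 >= cfg$plant_floor)
    if (length(eligible) < n_hits) {
      # fall back to the best-covered clones when the floor is unreachable
      eligible <- order(mu0, decreasing = TRUE)[seq_len(min(n, n_hits))]
    }
    enriched <- sort(sample(eligible, cfg$n_enriched))
    dual <- if (cfg$n_dual > 0L) sort(sample(enriched, cfg$n_dual)) else integer()
    depl_pool <- setdiff(eligible, enriched)
    depleted <- sort(c(dual, sample(depl_pool, cfg$n_depleted - cfg$n_dual)))

    # per-condition relative abundances: effects attach to the 2nd and 3rd
    # condition as configured (proliferation enrichment, then drug depletion)
    abund <- matrix(w, nrow = n, ncol = length(cfg$conditions),
                    dimnames = list(ids, cfg$conditions))
    if (length(cfg$conditions) >= 2L) {
      a <- abund[, 1L]
      a[enriched] <- a[enriched] * 2^cfg$log2_effect_enrich
      abund[, 2L] <- a
      if (length(cfg$conditions) >= 3L) {
        a3 <- a
        a3[depleted] <- a3[depleted] * 2^(-cfg$log2_effect_deplete)
        abund[, 3L] <- a3
        if (length(cfg$conditions) > 3L) {
          abund[, 4:ncol(abund)] <- a3
        }
      }
    }

    expected_mu <- apply(abund, 2L, function(a) cfg$depth * a / sum(a))
    dimnames(expected_mu) <- dimnames(abund)

    counts <- matrix(0L, nrow = n,
                     ncol = length(cfg$conditions) * cfg$n_replicates)
    cn <- character(ncol(counts))
    j <- 0L
    for (cond in cfg$conditions) {
      mu <- expected_mu[, cond]
      for (r in seq_len(cfg$n_replicates)) {
        j <- j + 1L
        cn[j] <- sprintf("%s_rep%d", cond, r)
        counts[, j] <- if (cfg$dispersion > 0) {
          stats::rnbinom(n, mu = mu, size = 1 / cfg$dispersion)
        } else {
          stats::rpois(n, lambda = mu)
        }
      }
    }
    dimnames(counts) <- list(ids, cn)

    is_hit <- seq_len(n) %in% union(enriched, depleted)
    sequences <- character(n)
    for (i in seq_len(n)) {
      sequences[i] <- if (is_hit[i]) {
        .random_seq_with_motif(22L, cfg$motif)
      } else {
        .random_seq_without_motif(22L, cfg$motif)
      }
    }

    list(
      table = screen_count_table(counts),
      catalogue = data.frame(mirna_id = ids, sequence = sequences),
      truth = list(
        enriched_ids = ids[enriched],
        depleted_ids = ids[depleted],
        dual_ids = ids[dual],
        motif = cfg$motif,
        expected_mu = expected_mu,
        seed_used = cfg$seed
      )
    )
  })
}
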