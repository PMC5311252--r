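.normalize_rna <- function(x) {
  x <- chartr("tT", "uU", x)
  x <- toupper(x)
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop("non-ACGU(T) character in sequence(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  x
}

.catalogue_seeds <- function(catalogue, region = c(1L, 8L)) {
  stats::setNames(extract_seed(catalogue$sequence, region = region),
                  catalogue$mirna_id)
}

#' Extract the seed region of mature miRNA sequences
#'
#' The seed is defined as 5' nucleotides 1-8 of the mature miRNA (the region
#' that base-pairs with mRNA 3'UTRs). Sequences are case-normalized and DNA
#' alphabet is coerced (T to U). An alternative region such as 2-8 can be
#' requested for comparability with other seed conventions.
#'
#' @param x character vector of mature sequences (length >= region end).
#' @param region integer pair, 1-based inclusive positions (default 1-8).
#' @return character vector of seed strings.
#' @examples
#' extract_seed("ACGUACGUACGU")
#' extract_seed("aaagugcugcgacauuugagcgu")  # miR-372-3p-like, DNA case mix ok
#' @export
extract_seed <- function(x, region = c(1L, 8L)) {
  stopifnot(length(region) == 2L, region[1] >= 1L, region[2] >= region[1])
  x <- .normalize_rna(x)
  if (any(nchar(x) < region[2])) {
    stop("sequence(s) shorter than the seed region (", region[2], " nt)")
  }
  substr(x, region[1], region[2])
}

#' Shared k-mer motifs among screen-hit seeds
#'
#' Enumerates every k-mer occurring within the seed (nt 1-8) of any hit
#' miRNA, and counts how many hit seeds and how many catalogue (background)
#' seeds contain it. A hypergeometric enrichment p-value against the
#' catalogue is attached per motif (see [motif_enrichment()]). Rows are
#' sorted by hit count (descending), then lexicographically by motif.
#'
#' @param hit_ids character vector of hit miRNA ids (subset of catalogue).
#' @param catalogue data.frame with `mirna_id` and `sequence` columns
#'   (e.g. from [read_fasta()]).
#' @param k motif length, between 1 and 8 (default 6).
#' @param region seed region passed to [extract_seed()].
#' @return data.frame with columns `motif`, `hit_count`, `background_count`,
#'   `p_value`.
#' @examples
#' cat <- data.frame(
#'   mirna_id = c("a", "b", "c"),
#'   sequence = c("AAGUGCAAUUUUUUUUUUUUUU", "AAGUGCGGUUUUUUUUUUUUUU",
#'                "CCCCCCCCUUUUUUUUUUUUUU"))
#' find_shared_motifs(c("a", "b"), cat)[1, ]
#' @export
find_shared_motifs <- function(hit_ids, catalogue, k = 6L,
                               region = c(1L, 8L)) {
  if (length(hit_ids) == 0L) stop("empty hit set")
  if (k < 1L || k > (region[2] - region[1] + 1L)) {
    stop("'k' must lie between 1 and the seed length")
  }
  if (!all(hit_ids %in% catalogue$mirna_id)) {
    stop("hit ids absent from the catalogue: ",
         paste(setdiff(hit_ids, catalogue$mirna_id), collapse = ", "))
  }
  seeds <- .catalogue_seeds(catalogue, region)
  seed_len <- region[2] - region[1] + 1L
  offsets <- seq_len(seed_len - k + 1L)
  kmers_of <- function(s) unique(substring(s, offsets, offsets + k - 1L))

  hit_kmers <- unique(unlist(lapply(seeds[hit_ids], kmers_of)))
  hit_counts <- vapply(hit_kmers, function(m) {
    sum(vapply(seeds[hit_ids], grepl, logical(1), pattern = m, fixed = TRUE))
  }, integer(1))
  bg_counts <- vapply(hit_kmers, function(m) {
    sum(vapply(seeds, grepl, logical(1), pattern = m, fixed = TRUE))
  }, integer(1))
  p <- vapply(hit_kmers, function(m) {
    motif_enrichment(m, hit_ids, catalogue, region = region)
  }, numeric(1))

  out <- data.frame(motif = hit_kmers, hit_count = hit_counts,
                    background_count = bg_counts, p_value = p,
                    row.names = NULL)
  out[order(-out$hit_count, out$motif), , drop = FALSE]
}

#' Hypergeometric motif enrichment among hits
#'
#' Quantifies whether a seed motif is over-represented among screen hits
#' relative to the library: `p = P(X >= x)` for
#' `X ~ Hypergeometric(N = catalogue size, K = seeds containing the motif,
#' n = number of hits)`, where `x` is the number of hit seeds containing the
#' motif. This quantification layer extends the qualitative shared-motif
#' observation.
#'
#' @param motif seed k-mer (length <= seed length).
#' @param hit_ids hit miRNA ids (subset of catalogue).
#' @param catalogue data.frame with `mirna_id`, `sequence`.
#' @param region seed region (default nt 1-8).
#' @return upper-tail hypergeometric p-value.
#' @export
motif_enrichment <- function(motif, hit_ids, catalogue,
                             region = c(1L, 8L)) {
  motif <- .normalize_rna(motif)
  if (nchar(motif) > (region[2] - region[1] + 1L)) {
    stop("'motif' longer than the seed region")
  }
  if (!all(hit_ids %in% catalogue$mirna_id)) {
    stop("hit ids must be a subset of the catalogue")
  }
  seeds <- .catalogue_seeds(catalogue, region)
  has <- grepl(motif, seeds, fixed = TRUE)
  N <- length(seeds)
  K <- sum(has)
  n <- length(hit_ids)
  x <- sum(has[match(hit_ids, catalogue$mirna_id)])
  stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Assign the seed family of a motif across a catalogue
#'
#' All catalogue miRNAs whose seed (nt 1-8) contains the motif, with the
#' 0-based offset of the first occurrence within the seed. Members are
#' ordered by id for determinism.
#'
#' @param catalogue data.frame with `mirna_id`, `sequence`.
#' @param motif seed k-mer.
#' @param region seed region (default nt 1-8).
#' @return object of class `seed_family`: list with `motif` and `members`
#'   (data.frame `mirna_id`, `offset`).
#' @examples
#' path <- system.file("extdata", "oncomotif_hits.fasta", package = "oncomotif")
#' fam <- assign_seed_family(read_fasta(path), "AAGUGC")
#' nrow(fam$members)
#' @export
assign_seed_family <- function(catalogue, motif, region = c(1L, 8L)) {
  motif <- .normalize_rna(motif)
  if (nchar(motif) > (region[2] - region[1] + 1L)) {
    stop("'motif' longer than the seed region")
  }
  seeds <- .catalogue_seeds(catalogue, region)
  pos <- regexpr(motif, seeds, fixed = TRUE)
  keep <- pos > 0L
  members <- data.frame(
    mirna_id = catalogue$mirna_id[keep],
    offset = as.integer(pos[keep]) - 1L
  )
  members <- members[order(members$mirna_id), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(motif = motif, members = members), class = "seed_family")
}

#' @export
print.seed_family <- function(x, ...) {
  cat(sprintf("seed_family '%s': %d member(s)\n", x$motif, nrow(x$members)))
  invisible(x)
}

#' Member ids of a seed family
#'
#' @param family a `seed_family` or a character vector of ids (returned
#'   unchanged).
#' @return character vector of miRNA ids.
#' @export
family_members <- function(family) {
  if (inherits(family, "seed_family")) family$members$mirna_id
  else as.character(family)
}
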