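#' Read a labelled numeric matrix from TSV
#'
#' Tab-separated table with a header row and row labels in the first
#' column. Duplicate row labels are an error (named), decimal points only.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, fill = FALSE,
                          stringsAsFactors = FALSE)
  labels <- as.character(df[[1L]])
  dup <- labels[duplicated(labels)]
  if (length(dup) > 0L) {
    stop("duplicate row label(s): ", paste(unique(dup), collapse = ", "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- labels
  m
}

#' Write a labelled matrix as TSV
#'
#' Counterpart of [read_matrix()]; row labels go into a first column named
#' `id`, full double precision is kept.
#'
#' @param x matrix with dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mature miRNA catalogue from FASTA
#'
#' The record id is the first whitespace-delimited token of the header;
#' sequences may wrap over multiple lines, are case-normalized, and DNA
#' alphabet is coerced (T to U). Empty records or characters outside
#' ACGU(T) are errors.
#'
#' @param path FASTA file path.
#' @return data.frame with `mirna_id` and `sequence` columns.
#' @examples
#' path <- system.file("extdata", "oncomotif_hits.fasta", package = "oncomotif")
#' read_fasta(path)$mirna_id
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate miRNA id(s) in ", path)
  seqs <- unname(as.character(set))
  if (any(nchar(seqs) == 0L)) stop("empty FASTA record in ", path)
  data.frame(mirna_id = ids, sequence = .normalize_rna(seqs))
}

#' Write a miRNA catalogue as FASTA
#'
#' @param catalogue data.frame with `mirna_id`, `sequence`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(catalogue, path) {
  writeLines(
    paste0(">", catalogue$mirna_id, "\n", catalogue$sequence),
    path
  )
  invisible(path)
}

#' Read a screen count table from TSV
#'
#' Column names must encode the design as `Condition_rep#`.
#'
#' @param path TSV file path.
#' @return a [screen_count_table()].
#' @export
read_screen_counts <- function(path) {
  m <- read_matrix(path)
  storage.mode(m) <- "integer"
  screen_count_table(m)
}

#' Read cohort sample metadata from TSV
#'
#' Validates the metadata column contract shared with [generate_cohort()].
#'
#' @param path TSV file path.
#' @return data.frame with at least `sample_id`, `is_tumor`, `TP53_mut`,
#'   `MYC_gain`, `rfs_time`, `rfs_event`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "is_tumor", "TP53_mut", "MYC_gain",
                "rfs_time", "rfs_event")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "))
  }
  df$is_tumor <- as.logical(df$is_tumor)
  df
}
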