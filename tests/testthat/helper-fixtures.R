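# Shared fixture builders for the test suite. Everything is constructed in
# code; the only file fixture is the packaged 4-miRNA FASTA.

oncomotif_fasta <- function() {
  system.file("extdata", "oncomotif_hits.fasta", package = "oncomotif")
}

# a screen_count_table from an explicit per-condition count list, three
# replicates each; rows named v1, v2, ...
make_screen_table <- function(...) {
  conds <- list(...)
  counts <- do.call(cbind, conds)
  colnames(counts) <- unlist(lapply(names(conds), function(cn) {
    sprintf("%s_rep%d", cn, seq_len(ncol(conds[[cn]])))
  }))
  rownames(counts) <- sprintf("v%d", seq_len(nrow(counts)))
  screen_count_table(counts)
}

# small random catalogue over the RNA alphabet (seeded by caller)
random_catalogue <- function(n, len = 22L) {
  data.frame(
    mirna_id = sprintf("m%02d", seq_len(n)),
    sequence = vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
            collapse = "")
    }, "")
  )
}

# adjusted Rand index between two labelings (closed-form, pair-counting)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
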