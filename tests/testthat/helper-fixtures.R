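# Small in-code fixtures shared across tests.

tiny_matrix <- function() {
  counts <- matrix(c(3L, 0L, 1L, 2L,
                     1L, 5L, 0L, 0L), nrow = 2, byrow = TRUE)
  count_matrix(counts, gene_ids = c("GENEA", "MT-1"),
               barcodes = sprintf("BC%d", 1:4), sample = "S1")
}

# Genes x cells matrix of Poisson counts driven by a shared latent factor:
# planted rows load on the factor with `loading`, null rows do not.
latent_factor_counts <- function(n_planted, n_null, n_cells, loading = 0.5,
                                 seed = 1) {
  set.seed(seed)
  z <- stats::rnorm(n_cells)
  tag <- stats::rpois(n_cells, exp(0.5 + loading * z))
  planted <- t(vapply(seq_len(n_planted), function(i) {
    stats::rpois(n_cells, exp(0.3 + loading * z))
  }, numeric(n_cells)))
  null <- matrix(stats::rpois(n_null * n_cells, 1.5), nrow = n_null)
  counts <- rbind(matrix(tag, nrow = 1), planted, null)
  rownames(counts) <- c("TAG", sprintf("PLANT%03d", seq_len(n_planted)),
                        sprintf("NULL%03d", seq_len(n_null)))
  counts
}
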