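# Small in-code fixtures shared across tests.

# a tiny deterministic record set with hand-controlled sequences
tiny_records <- function() {
  list(
    g1 = gene_seq_record("g1", utr5 = "CCA", cds = "ATGGCTAAATAA",
                         utr3 = "CGGT"),
    g2 = gene_seq_record("g2", utr5 = "", cds = "ATGAAACCCGGGTGA",
                         utr3 = ""),
    g3 = gene_seq_record("g3", utr5 = "TTTTT", cds = "ATGTTTTAA",
                         utr3 = "AA")
  )
}

# small random dataset with exact linear structure + optional noise
toy_dataset <- function(n_genes = 10, n_tissues = 8, a = NULL, b = NULL,
                        noise_sd = 0, missing = 0, seed = 1) {
  set.seed(seed)
  if (is.null(a)) a <- runif(n_genes, 0.3, 1)
  if (is.null(b)) b <- runif(n_genes, 8, 12)
  x <- matrix(rnorm(n_genes * n_tissues, 3, 2), n_genes)
  y <- x * a + b + matrix(rnorm(n_genes * n_tissues, 0, noise_sd), n_genes)
  if (missing > 0) {
    x[matrix(runif(n_genes * n_tissues) < missing, n_genes)] <- NA
    y[matrix(runif(n_genes * n_tissues) < missing, n_genes)] <- NA
  }
  rownames(x) <- rownames(y) <- paste0("g", seq_len(n_genes))
  colnames(x) <- colnames(y) <- paste0("t", seq_len(n_tissues))
  list(dataset = ptr_dataset(x, y), a = a, b = b)
}

# deterministic small synthetic simulation reused by several tests
small_sim <- function(seed = 1, n_genes = 60, n_tissues = 12) {
  generate_synthetic(generative_spec(n_genes = n_genes, n_tissues = n_tissues,
                                     utr5_len = c(30, 60), cds_len = c(90, 150),
                                     utr3_len = c(30, 60), seed = seed))
}
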