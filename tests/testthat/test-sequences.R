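test_that("one_hot_encode produces indicator columns with zero padding", {
  m <- one_hot_encode("ACGT", pad_to = 4)
  expect_equal(unname(m), diag(4))
  m2 <- one_hot_encode("AN", pad_to = 3)
  expect_equal(unname(m2[, 1]), c(1, 0, 0, 0))
  expect_equal(colSums(m2), c(1, 0, 0))   # N and padding are all-zero
  # column sums always 0 or 1; re-padding only appends zero columns
  set.seed(2)
  s <- paste(sample(c("A", "C", "G", "T", "N"), 20, TRUE), collapse = "")
  a <- one_hot_encode(s, pad_to = 25)
  b <- one_hot_encode(s, pad_to = 40)
  expect_true(all(colSums(a) %in% c(0, 1)))
  expect_equal(b[, 1:25], a)
  expect_equal(sum(b[, 26:40]), 0)
})

test_that("codon_counts respects frame shift and discards partial triplets", {
  cc <- codon_counts("ATGATG", 0)
  expect_equal(cc[["ATG"]], 2L)
  expect_equal(sum(cc), 2L)
  cc1 <- codon_counts("ATGATG", 1)
  expect_equal(cc1[["TGA"]], 1L)
  expect_equal(sum(cc1), 1L)              # trailing "TG" dropped
  # oracle: direct triplet enumeration on a random 300-nt sequence
  set.seed(9)
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  for (shift in 0:2) {
    expect_equal(sum(codon_counts(s, shift)), (300 - shift) %/% 3)
    starts <- seq(shift + 1, 300 - 2, by = 3)
    oracle <- table(substring(s, starts, starts + 2))
    cc <- codon_counts(s, shift)
    expect_equal(cc[names(oracle)], setNames(as.integer(oracle),
                                             names(oracle)))
  }
})

test_that("nucleotide and amino-acid counts are simple histograms", {
  expect_equal(nucleotide_counts("AACG"),
               c(A = 2L, C = 1L, G = 1L, T = 0L))
  aa <- amino_acid_counts("MKK")
  expect_equal(aa[["M"]], 1L)
  expect_equal(aa[["K"]], 2L)
  expect_equal(sum(aa), 3L)
  expect_equal(sum(nucleotide_counts("")), 0L)
  expect_equal(sum(amino_acid_counts("")), 0L)
})

test_that("translate_cds follows the standard code and stop rules", {
  expect_equal(translate_cds("ATGAAATAA"), "MK")
  expect_equal(translate_cds("ATGTGA"), "M")
  expect_warning(p <- translate_cds("ATGTAAAAATAA"), "internal stop")
  expect_equal(p, "M")
  expect_error(translate_cds("ATGA"), "divisible")
})

test_that("codon counts aggregate to amino-acid counts through the code", {
  set.seed(11)
  sim <- small_sim(seed = 11, n_genes = 8)
  code <- Biostrings::GENETIC_CODE
  for (r in sim$records[1:5]) {
    cc <- codon_counts(r$cds, 0)
    agg <- tapply(cc, code[names(cc)], sum)
    agg <- agg[names(agg) != "*"]
    aa <- amino_acid_counts(r$protein)
    expect_equal(unname(aa[names(agg)]), unname(as.integer(agg)))
  }
})

test_that("codon_context windows anchor correctly with padding", {
  r <- gene_seq_record("g", utr5 = "GGCA", cds = "ATGGCTTTTTAA", utr3 = "CGGA")
  # start anchor, w_up=2 w_down=3: window CA | ATG | GCT
  v <- codon_context(r, "start", w_up = 2, w_down = 3)
  m <- matrix(v, 4, byrow = TRUE, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(paste(rownames(m)[apply(m, 2, which.max)], collapse = ""),
               "CAATGGCT")
  # empty UTR gives leading all-zero columns
  r2 <- gene_seq_record("g2", utr5 = "", cds = "ATGGCTTTTTAA")
  v2 <- codon_context(r2, "start", w_up = 2, w_down = 3)
  m2 <- matrix(v2, 4, byrow = TRUE)
  expect_equal(sum(m2[, 1:2]), 0)
  expect_equal(sum(m2[, 3:8]), 6)
  # stop anchor: downstream window drawn from the 3'UTR
  r3 <- gene_seq_record("g3", utr5 = "A", cds = "ATGGCTTAA", utr3 = "CGGTT")
  v3 <- codon_context(r3, "stop", w_up = 2, w_down = 3)
  m3 <- matrix(v3, 4, byrow = TRUE, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(paste(rownames(m3)[apply(m3, 2, which.max)], collapse = ""),
               "CTTAACGG")
})

test_that("FASTA round trip preserves sequences keyed by gene ID", {
  td <- withr::local_tempdir()
  recs <- tiny_records()
  write_gene_sequences(recs, td)
  back <- read_gene_sequences(cds_fasta = file.path(td, "cds.fa"),
                              utr5_fasta = file.path(td, "utr5.fa"),
                              utr3_fasta = file.path(td, "utr3.fa"),
                              protein_fasta = file.path(td, "pep.fa"))
  expect_equal(names(back), names(recs))
  for (id in names(recs)) {
    expect_equal(back[[id]]$cds, recs[[id]]$cds)
    expect_equal(back[[id]]$utr5, recs[[id]]$utr5)
    expect_equal(back[[id]]$protein, recs[[id]]$protein)
  }
})

test_that("encode_features builds aligned matrices for all eight features", {
  recs <- tiny_records()
  fb <- encode_features(recs, w_up = 2, w_down = 3)
  expect_equal(fb$gene_ids, c("g1", "g2", "g3"))
  expect_equal(dim(fb$counts$codon_f0), c(3, 64))
  expect_equal(dim(fb$counts$aa), c(3, 20))
  expect_equal(dim(fb$counts$start_context), c(3, 4 * 8))
  # one-hot padded to the max observed length per region
  expect_equal(ncol(fb$onehot$utr5[[1]]), 5)
  expect_equal(ncol(fb$onehot$cds[[1]]), 15)
  # empty region encodes to an all-zero matrix
  expect_equal(sum(fb$onehot$utr5[[2]]), 0)
})
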