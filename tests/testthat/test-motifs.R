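test_that("standardize_filters yields zero mean, unit sd; drops constants", {
  bank <- structure(list(feature = "utr5", filters = list(
    f1 = matrix(c(1, 3, 1, 3), 2, 2),
    f2 = matrix(2, 2, 2),
    f3 = matrix(rnorm(8), 2, 4))), class = "filter_bank")
  expect_warning(out <- standardize_filters(bank), "constant")
  expect_named(out$filters, c("f1", "f3"))
  for (f in out$filters) {
    expect_equal(mean(f), 0, tolerance = 1e-12)
    expect_equal(sd(as.vector(f)), 1, tolerance = 1e-12)
  }
})

test_that("positional masking keeps the informative span, strict cutoff", {
  f <- cbind(c(0, 0, 0, 0), c(1, -1, 1, -1), c(0.1, -0.1, 0.1, -0.1),
             c(2, -2, 2, -2), c(0, 0, 0, 0))
  tr <- mask_informative_positions(f, std_cutoff = 0.2)
  expect_equal(tr$kept, c(2, 4))
  expect_equal(ncol(tr$filter), 3)     # internal low-sd column retained
  # a column with sd exactly at the cutoff is dropped (strict >)
  v <- c(-1, 1, -1, 1)
  f2 <- cbind(v, c(5, -5, 5, -5))
  tr2 <- mask_informative_positions(f2, std_cutoff = sd(v))
  expect_equal(tr2$kept, c(2, 2))
  expect_null(mask_informative_positions(matrix(0, 4, 3)))
})

test_that("offset enumeration produces all placements with bookkeeping", {
  f <- matrix(1:8, 4, 2)
  out <- enumerate_offsets(f, 6)
  expect_length(out, 5)               # W - k + 1
  for (i in seq_along(out)) {
    off <- attr(out[[i]], "offset")
    expect_equal(out[[i]][, (off + 1):(off + 2)], unname(f))
    expect_equal(sum(out[[i]]) , sum(f))
  }
  one <- enumerate_offsets(f, 2)
  expect_length(one, 1)
  expect_equal(one[[1]][, 1:2], unname(f))
  expect_error(enumerate_offsets(f, 1), "narrower")
})

test_that("optics_xi recovers planted well-separated clusters", {
  set.seed(15)
  c1 <- matrix(rnorm(40 * 5, 0, 0.05), ncol = 5)
  c2 <- matrix(rnorm(40 * 5, 3, 0.05), ncol = 5)
  c3 <- matrix(rnorm(40 * 5, -3, 0.05), ncol = 5)
  X <- rbind(c1, c2, c3)
  res <- optics_xi(X, min_samples = 5, xi = 0.05)
  truth <- rep(1:3, each = 40)
  cl <- res$labels
  # points of different planted groups never share a label
  for (k in unique(cl[cl >= 0]))
    expect_equal(length(unique(truth[cl == k])), 1)
  # the cluster hierarchy contains each full blob as one cluster
  ranges <- apply(res$clusters, 1, function(z)
    paste(sort(unique(truth[res$ordering[z[1]:z[2]]])), collapse = "+"))
  sizes <- res$clusters[, 2] - res$clusters[, 1] + 1
  for (b in c("1", "2", "3"))
    expect_true(any(ranges == b & sizes == 40))
})

test_that("optics_xi agrees with the scikit-learn implementation", {
  set.seed(16)
  X <- rbind(matrix(rnorm(60 * 4, 0, 0.1), ncol = 4),
             matrix(rnorm(60 * 4, 2, 0.1), ncol = 4))
  res <- optics_xi(X, min_samples = 5, xi = 0.05)
  tf <- tempfile(fileext = ".csv")
  utils::write.table(X, tf, row.names = FALSE, col.names = FALSE, sep = ",")
  out <- system2("python", c("-c", shQuote(paste0(
    "import numpy as np; from sklearn.cluster import OPTICS; ",
    "X = np.loadtxt('", tf, "', delimiter=','); ",
    "o = OPTICS(min_samples=5, xi=0.05, metric='euclidean').fit(X); ",
    "print(','.join(map(str, o.labels_)))"))), stdout = TRUE)
  skl <- as.integer(strsplit(tail(out, 1), ",")[[1]])
  expect_equal(res$labels, skl)
})

test_that("cluster_filters separates two planted motifs across offsets", {
  set.seed(17)
  m1 <- one_hot_encode("GCACGTGG", pad_to = 8) * 2 - 0.5
  m2 <- one_hot_encode("TTATTAGC", pad_to = 8) * 2 - 0.5
  padded <- list()
  for (i in 1:30) {
    src <- if (i %% 2 == 0) m1 else m2
    noisy <- src + matrix(rnorm(32, 0, 0.03), 4)
    for (p in enumerate_offsets(noisy, 10)) {
      attr(p, "source") <- paste0("f", i)
      padded[[length(padded) + 1]] <- p
    }
  }
  labels <- cluster_filters(padded, "nucleotide")
  expect_gte(length(unique(labels[labels >= 0])), 2)
  src_motif <- rep(rep(c("m2", "m1"), 15), each = 3)
  for (k in unique(labels[labels >= 0]))
    expect_equal(length(unique(src_motif[labels == k])), 1)
})

test_that("dedup keeps each source filter only in its best-ranked cluster", {
  mk <- function(src) {
    m <- matrix(1, 2, 2); attr(m, "source") <- src; m
  }
  padded <- list(mk("a"), mk("a"), mk("b"), mk("c"), mk("a"), mk("d"))
  labels <- c(0L, 0L, 0L, 1L, 1L, 1L)
  out <- dedup_and_rank(labels, padded)
  # cluster 0 ({a,a,b}) dedups to {a,b}; cluster 1 ({c,a,d}) loses a
  expect_equal(sort(out[[1]]$sources), c("a", "b"))
  expect_equal(sort(out[[2]]$sources), c("c", "d"))
  n_src <- length(unique(c("a", "b", "c", "d")))
  expect_lte(sum(lengths(lapply(out, `[[`, "sources"))), n_src)
  # unique memberships come back sorted by size
  labels2 <- c(0L, 1L, 1L, -1L, 1L, 2L)
  padded2 <- list(mk("a"), mk("b"), mk("c"), mk("d"), mk("e"), mk("f"))
  out2 <- dedup_and_rank(labels2, padded2)
  expect_equal(vapply(out2, function(cl) length(cl$sources), 0L), c(3L, 1L, 1L))
})

test_that("normalize_cluster scales the peak to 1, trims, and recentres", {
  m <- matrix(0, 4, 9); m[2, 3] <- 0.5; m[3, 4] <- 0.25; m[1, 8] <- 0.04
  cl <- list(members = list(m), sources = "f1")
  mc <- normalize_cluster(cl, "utr5", 1)
  expect_equal(max(mc$consensus), 1)
  # peak recentred to the middle column
  expect_equal(unname(which(mc$consensus == 1, arr.ind = TRUE)[1, ]),
               c(2, 5))
  # entries <= 0.1 after scaling are removed (0.04/0.5 = 0.08 <= 0.1)
  expect_equal(sum(mc$consensus > 0), 2)
  expect_equal(mc$consensus[3, 6], 0.5)
  # averaging identity for single-member clusters, exact 1 maximum
  set.seed(18)
  mm <- matrix(runif(36), 4, 9)
  mc2 <- normalize_cluster(list(members = list(mm), sources = "x"), "cds", 2)
  expect_equal(max(mc2$consensus), 1)
})

test_that("entry exactly at 0.1 of the peak is removed", {
  m <- matrix(0, 4, 5); m[1, 3] <- 1; m[2, 1] <- 0.1; m[3, 2] <- 0.100001
  mc <- normalize_cluster(list(members = list(m), sources = "s"), "utr3", 1)
  expect_equal(mc$consensus[2, 1], 0)
  expect_gt(mc$consensus[3, 2], 0)
})

test_that("gradient weight extraction composes affine maps exactly", {
  sim <- small_sim(seed = 71, n_genes = 25)
  feats <- encode_features(sim$records)
  m <- ptr_model(list(dense_branch("codon_f0")), feats, seed = 1)
  m <- train_ptr_model(m, sim$dataset, feats, lr = 1e-3, epochs = 5, seed = 1)
  w <- extract_gradient_weights(list(m), feats)$codon_f0
  expect_equal(unname(w), unname(m$head$final$W[1, ]), tolerance = 1e-12)
  # averaging two models with opposite weights gives zero
  m2 <- m
  m2$head$final$W <- -m$head$final$W
  w2 <- extract_gradient_weights(list(m, m2), feats)$codon_f0
  expect_equal(unname(w2), rep(0, 64))
})

test_that("offset-enumerated clustering is shift-consistent", {
  set.seed(19)
  f <- matrix(rnorm(32), 4, 8)
  a <- enumerate_offsets(f, 12)
  shifted <- cbind(matrix(0, 4, 2), f[, 1:6])  # same content pre-shifted
  # placements of the same trimmed filter content at matching offsets agree
  expect_equal(a[[3]][, 3:10], unname(f))
  expect_equal(a[[1]][, 1:8], a[[5]][, 5:12])
})

test_that("write_meme emits parseable minimal MEME output", {
  m <- matrix(0, 4, 5, dimnames = list(c("A", "C", "G", "T"), NULL))
  m[1, 2] <- 1; m[2, 3] <- 0.6
  mc <- structure(list(consensus = m, n_members = 7, source_feature = "utr5",
                       rank = 1), class = "motif_cluster")
  tf <- tempfile(fileext = ".meme")
  write_meme(list(mc), tf)
  lines <- readLines(tf)
  expect_true(any(grepl("^MEME version", lines)))
  expect_true(any(grepl("^MOTIF utr5_cluster1_n7", lines)))
  expect_true(any(grepl("letter-probability matrix: alength= 4 w= 2", lines)))
})
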