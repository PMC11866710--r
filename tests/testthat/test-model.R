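test_that("nan_safe_mse equals filter-then-MSE on random masked instances", {
  pred <- matrix(c(1, 3, 2, 4), 2, 2)
  target <- matrix(c(1, 3, 0, 0), 2, 2)
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(nan_safe_mse(pred, target, mask), 0)
  # no missing cells: ordinary MSE
  set.seed(1)
  p <- matrix(rnorm(20), 4); t0 <- matrix(rnorm(20), 4)
  expect_equal(nan_safe_mse(p, t0, matrix(TRUE, 4, 5)), mean((p - t0)^2))
  # oracle loop
  set.seed(2)
  for (i in 1:200) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    p <- matrix(rnorm(n * m), n)
    y <- matrix(rnorm(n * m), n)
    mask <- matrix(runif(n * m) < 0.7, n)
    if (sum(mask) == 0) next
    expect_equal(nan_safe_mse(p, y, mask),
                 mean((p[mask] - y[mask])^2), tolerance = 1e-12)
  }
  expect_error(nan_safe_mse(p, y, mask & FALSE), "no valid cells")
  expect_warning(z <- nan_safe_mse(p, y, mask & FALSE, on_empty = "zero"),
                 "zero loss")
  expect_equal(z, 0)
})

test_that("predict_log2_ibaq reproduces the linear PTR equation", {
  expect_equal(predict_log2_ibaq(list(a = 1, b = 0), 5), 5)
  expect_equal(predict_log2_ibaq(list(a = 0, b = 7), 123), 7)
  expect_equal(predict_log2_ibaq(list(a = 0.5, b = 1, delta = 0.5), 3,
                                 context_log2_tpm = 2), 3.5)
  expect_true(is.na(predict_log2_ibaq(list(a = 1, b = 0), NA)))
  expect_error(predict_log2_ibaq(list(a = 1, b = 0, delta = c(1, 2)), 1,
                                 context_log2_tpm = 3), "length")
})

test_that("r2_per_gene matches its defining formula", {
  pred <- rbind(c(1, 2, 3), c(0, 0, 0), c(2, 2, 2))
  targ <- rbind(c(1, 2, 3), c(0, 1, 2), c(5, 5, 5))
  rownames(pred) <- rownames(targ) <- c("gA", "gB", "gC")
  sc <- r2_per_gene(pred, targ)
  expect_equal(sc$scores[["gA"]], 1)              # perfect prediction
  expect_equal(sc$scores[["gB"]], 1 - 5 / 2)      # direct formula
  expect_true(is.na(sc$scores[["gC"]]))           # zero target variance
  expect_equal(sc$n_undefined, 1)
  # predicting the gene mean scores exactly 0
  pred2 <- matrix(1, 1, 3); targ2 <- matrix(c(0, 1, 2), 1)
  expect_equal(unname(r2_per_gene(pred2, targ2)$scores), 0)
})

test_that("dense_branch_forward applies log2(1+x) then an affine map", {
  W <- matrix(0, 2, 3)
  expect_equal(dense_branch_forward(c(0, 0, 0), W, b = c(4, 5)), c(4, 5))
  W2 <- matrix(1:6, 2, 3)
  expect_equal(dense_branch_forward(c(1, 0, 0), W2, b = 0)[1], 1)  # log2(2)=1
  set.seed(3)
  v <- rexp(5); W3 <- matrix(rnorm(10), 2, 5); b3 <- rnorm(2)
  expect_equal(dense_branch_forward(v, W3, b3),
               as.vector(W3 %*% log2(1 + v) + b3), tolerance = 1e-12)
  expect_error(dense_branch_forward(1:3, matrix(0, 2, 4)), "length")
})

test_that("conv_branch_forward matches a hand-rolled computation", {
  # 1 filter, width 2, alphabet 4, length-4 one-hot
  oh <- one_hot_encode("ACGA", pad_to = 4)
  w <- matrix(seq(-0.4, 0.3, length.out = 8), ncol = 1)  # flattened 4x2 filter
  out <- conv_branch_forward(oh, w, bias = 0.1, width = 2)
  fm <- matrix(w, 4, 2)
  z <- sapply(1:3, function(i) sum(fm * oh[, i:(i + 1)])) + 0.1
  expect_equal(out, log2(1 + sum(pmax(tanh(z), 0))), tolerance = 1e-12)
  # all-zero input with zero bias gives exactly 0
  expect_equal(conv_branch_forward(matrix(0, 4, 6), w, 0, width = 2), 0)
})

test_that("conv pooled output is invariant to motif position in padding", {
  set.seed(4)
  w <- matrix(rnorm(32), ncol = 1)
  base <- matrix(0, 4, 60)
  motif <- one_hot_encode("GCACGTGG", pad_to = 8)
  m1 <- base; m1[, 10:17] <- motif
  m2 <- base; m2[, 40:47] <- motif
  expect_identical(conv_branch_forward(m1, w, 0, width = 8),
                   conv_branch_forward(m2, w, 0, width = 8))
})

test_that("head output width is 2 plus the number of context genes", {
  sim <- small_sim(seed = 21, n_genes = 30)
  feats <- encode_features(sim$records)
  m0 <- ptr_model(list(dense_branch("codon_f0")), feats, n_context_genes = 0)
  expect_equal(nrow(m0$head$final$W), 2)
  m3 <- ptr_model(list(dense_branch("codon_f0")), feats, n_context_genes = 3)
  expect_equal(nrow(m3$head$final$W), 5)
  p <- ptr_parameters(m3, feats, feats$gene_ids[1:4])
  expect_equal(ncol(p), 2 + 1 + 3)   # gene_id, a, b, delta.1..3
})

test_that("numerical gradient matches backpropagation on a tiny instance", {
  sim <- small_sim(seed = 31, n_genes = 12, n_tissues = 6)
  feats <- encode_features(sim$records)
  branches <- list(dense_branch("codon_f0"), conv_branch("utr5", 3, 4))
  model <- ptr_model(branches, feats, combine_widths = c(5), seed = 2)
  # randomize the (zero-initialized) final layer so gradients reach every
  # parameter group
  set.seed(22)
  model$head$final$W[] <- rnorm(length(model$head$final$W), 0, 0.3)
  design <- ptrnet:::build_design(model, feats)
  gi <- 1:6
  model$norm <- ptrnet:::compute_branch_norm(model, design, gi)
  model$x_center <- 0
  x <- sim$dataset$log2_tpm[gi, ]; y <- sim$dataset$log2_ibaq[gi, ]
  v <- sim$dataset$valid_mask[gi, ]
  loss_of <- function(m) {
    fwd <- ptrnet:::model_forward_batch(m, design, gi)
    lg <- ptrnet:::batch_loss_grad(fwd$out, x, y, v)
    lg$loss / lg$n
  }
  fwd <- ptrnet:::model_forward_batch(model, design, gi)
  lg <- ptrnet:::batch_loss_grad(fwd$out, x, y, v)
  grads <- ptrnet:::model_backward_batch(model, design, fwd, gi, lg$dOut)
  eps <- 1e-6
  check <- function(get, set, g_an) {
    th <- get(model)
    idx <- sample(length(th), min(5, length(th)))
    for (i in idx) {
      mp <- model; thp <- th; thp[i] <- thp[i] + eps
      mp <- set(mp, thp)
      mm <- model; thm <- th; thm[i] <- thm[i] - eps
      mm <- set(mm, thm)
      g_num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      expect_equal(g_num, g_an[i], tolerance = 1e-4)
    }
  }
  set.seed(5)
  check(function(m) m$params[[2]]$F,
        function(m, v) { m$params[[2]]$F[] <- v; m },
        as.vector(grads$params[[2]]$F))
  check(function(m) m$params[[1]]$W,
        function(m, v) { m$params[[1]]$W[] <- v; m },
        as.vector(grads$params[[1]]$W))
  check(function(m) m$head$final$W,
        function(m, v) { m$head$final$W[] <- v; m },
        as.vector(grads$head$final$W))
  check(function(m) m$head$hidden[[1]]$W,
        function(m, v) { m$head$hidden[[1]]$W[] <- v; m },
        as.vector(grads$head$hidden[[1]]$W))
})

test_that("training with zero epochs returns the initial weights", {
  sim <- small_sim(seed = 41, n_genes = 20)
  feats <- encode_features(sim$records)
  m0 <- ptr_model(list(dense_branch("codon_f0")), feats, seed = 9)
  m <- train_ptr_model(m0, sim$dataset, feats, epochs = 0, seed = 9)
  expect_equal(m$head$final$W, m0$head$final$W)
  expect_equal(length(attr(m, "loss_trace")), 0)
})

test_that("training reduces the loss on synthetic data, deterministically", {
  sim <- small_sim(seed = 51, n_genes = 40)
  feats <- encode_features(sim$records)
  run <- function() {
    m <- ptr_model(list(dense_branch("codon_f0")), feats, seed = 3)
    train_ptr_model(m, sim$dataset, feats, lr = 1e-3, epochs = 40, seed = 3)
  }
  m1 <- run(); m2 <- run()
  lt <- attr(m1, "loss_trace")
  expect_lt(tail(lt, 1), lt[1])
  expect_identical(m1$head$final$W, m2$head$final$W)  # seed determinism
})

test_that("cross_validate partitions the split axis and is seed-stable", {
  sim <- small_sim(seed = 61, n_genes = 40, n_tissues = 10)
  feats <- encode_features(sim$records)
  cv <- cross_validate(sim$dataset, feats, list(dense_branch("codon_f0")),
                       n_repeats = 2, n_folds = 5, lr = 1e-3, epochs = 10,
                       seed = 4, keep_models = FALSE)
  expect_equal(nrow(cv$scores), 10)                 # repeats x folds rows
  # each gene scored exactly once per repeat
  for (r in 1:2) {
    scored <- unlist(lapply(which(cv$scores$repeat_id == r), function(i)
      names(cv$gene_scores[[i]])))
    expect_setequal(scored, sim$dataset$gene_ids)
    expect_equal(anyDuplicated(scored), 0)
  }
  cv2 <- cross_validate(sim$dataset, feats, list(dense_branch("codon_f0")),
                        n_repeats = 2, n_folds = 5, lr = 1e-3, epochs = 10,
                        seed = 4, keep_models = FALSE)
  expect_identical(cv$scores, cv2$scores)
  expect_error(cross_validate(sim$dataset, feats,
                              list(dense_branch("codon_f0")),
                              n_folds = 12, split_axis = "tissues"),
               "fewer items")
})
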