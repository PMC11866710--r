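# Two-branch network predicting per-gene linear PTR parameters.
#
# Dense branches consume histogram-like features (counts get a log2(1+x)
# transform, context one-hots pass through unchanged); convolutional branches
# consume padded one-hot sequences via conv -> max(0, tanh) -> sum-pooling ->
# log2(1+s).  In single-feature models the branch output feeds the final
# affine layer directly; in combined models each branch has its own dense
# layer, followed by ReLU combine layers (widths 32 and 16) and the final
# affine layer with 2 + n_context_genes outputs (a, b, delta).  Training is
# plain SGD (no momentum) on a NaN-safe MSE over valid (gene, tissue) cells,
# with one gene per sample and batches of 32 genes.  Gradients are exact
# (hand-derived backpropagation).

#' Dense branch specification
#'
#' @param feature name of a count/context feature in [encode_features()]
#'   output (`codon_f0/f1/f2`, `nt_utr5`, `nt_cds`, `nt_utr3`, `aa`,
#'   `start_context`, `stop_context`).
#' @param apply_log2 apply log2(1 + x) to the input (TRUE for count
#'   histograms, FALSE for context one-hots).  Defaults to FALSE for the
#'   `*_context` features.
#' @return Branch specification list.
#' @export
dense_branch <- function(feature, apply_log2 = !grepl("context", feature)) {
  list(type = "dense", feature = feature, apply_log2 = apply_log2)
}

#' Convolutional branch specification
#'
#' @param feature one of `utr5`, `cds`, `utr3`, `pep`.
#' @param n_filters number of convolutional filters (default 16).
#' @param filter_width filter width in sequence positions (8, 10 or 12).
#' @return Branch specification list.
#' @export
conv_branch <- function(feature, n_filters = 16, filter_width = 8) {
  list(type = "conv", feature = feature, n_filters = n_filters,
       filter_width = filter_width)
}

glorot <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

branch_input_dim <- function(br, features) {
  if (br$type == "dense") ncol(features$counts[[br$feature]])
  else nrow(features$onehot[[br$feature]][[1]]) * br$filter_width
}

branch_output_dim <- function(br, features) {
  if (br$type == "dense") ncol(features$counts[[br$feature]]) else br$n_filters
}

#' Construct an untrained PTR model
#'
#' @param branches list of [dense_branch()] / [conv_branch()] specs.
#' @param features a `ptr_features` object (defines input dimensions).
#' @param n_context_genes number of context genes for the delta extension;
#'   the head emits `2 + n_context_genes` outputs.
#' @param combine_widths integer vector of combine-layer widths
#'   (`c(32, 16)` for the combined model, `NULL` for single-feature models).
#' @param branch_width latent width of per-branch dense layers in combined
#'   models (default 16).
#' @param seed RNG seed for weight initialization (uniform Glorot-style,
#'   scaled by fan-in/fan-out).
#' @param conv_init_scale multiplier on the Glorot limit for convolutional
#'   filters (default 1/3).  Starting the filters in the small-signal,
#'   near-linear regime of tanh lets the learned sequence structure, rather
#'   than the random initialization, dominate the trained filter, which is
#'   what the downstream filter-clustering step interprets.
#' @param conv_init_bias initial per-filter bias (default 0).  A slightly
#'   negative bias makes filters selective from the start: few windows pass
#'   the tanh/ReLU gate, so gradients concentrate on high-scoring windows
#'   instead of being diluted across the whole sequence.
#' @return Object of class `ptr_model`.
#' @export
ptr_model <- function(branches, features, n_context_genes = 0,
                      combine_widths = NULL, branch_width = 16, seed = 1,
                      conv_init_scale = 1 / 3, conv_init_bias = 0) {
  combined <- length(branches) > 1 || length(combine_widths) > 0
  set.seed(seed)
  n_out <- 2 + n_context_genes
  params <- vector("list", length(branches))
  latent_dims <- integer(length(branches))
  for (j in seq_along(branches)) {
    br <- branches[[j]]
    p <- list()
    if (br$type == "conv") {
      d_in <- branch_input_dim(br, features)
      p$F <- glorot(d_in, br$n_filters, d_in, br$n_filters) * conv_init_scale
      p$fb <- rep(conv_init_bias, br$n_filters)
    }
    q <- branch_output_dim(br, features)
    if (combined) {
      p$W <- glorot(branch_width, q, q, branch_width)
      p$b <- numeric(branch_width)
      latent_dims[j] <- branch_width
    } else {
      latent_dims[j] <- q
    }
    params[[j]] <- p
  }
  width_in <- sum(latent_dims)
  hidden <- list()
  for (w in combine_widths) {
    hidden[[length(hidden) + 1]] <- list(W = glorot(w, width_in, width_in, w),
                                         b = numeric(w))
    width_in <- w
  }
  # the final affine layer starts at zero: it has no symmetry to break, and
  # zero init keeps directions the data never constrains (e.g. exactly
  # collinear count features) at exactly zero weight, so extracted weight
  # maps show learned signal only
  head <- list(hidden = hidden,
               final = list(W = matrix(0, n_out, width_in),
                            b = numeric(n_out)))
  structure(list(branches = branches, params = params, head = head,
                 n_context_genes = n_context_genes, combined = combined,
                 seed = seed, norm = NULL),
            class = "ptr_model")
}

# Fixed per-dimension standardization of branch outputs (count transforms,
# pooled convolution vectors), estimated once on the training genes at
# initialization.  Keeps the optimization landscape well-conditioned so the
# configured learning rates behave consistently across feature types; the
# scaling is part of the model and reused verbatim at prediction time.
compute_branch_norm <- function(model, design, gi) {
  lapply(seq_along(model$branches), function(j) {
    br <- model$branches[[j]]
    if (br$type == "dense") {
      V <- design[[j]]$X[gi, , drop = FALSE]
    } else {
      pr <- model$params[[j]]
      V <- log2(1 + conv_pool(design[[j]], pr, gi)$S)
    }
    mu <- colMeans(V)
    sigma <- apply(V, 2, stats::sd)
    sigma[!is.finite(sigma) | sigma < 1e-8] <- 1
    # floor the per-dimension scale within a branch so near-degenerate
    # dimensions are not amplified into dominant inputs
    sigma <- pmax(sigma, 0.2 * mean(sigma))
    list(mu = mu, sigma = sigma)
  })
}

# ---- precomputed input design ---------------------------------------------

# im2col bank for one conv feature: rows = (gene, window position), columns =
# alphabet x filter_width cells in window-offset-major order (matches
# as.vector() of an alphabet x width filter matrix).
# All-zero windows (pure padding) are dropped from the bank and accounted
# for analytically: such a window contributes relu(tanh(bias)) to the pooled
# sum and a matching bias gradient, independent of the filter weights.
build_conv_bank <- function(onehot_list, width) {
  A <- nrow(onehot_list[[1]])
  L <- ncol(onehot_list[[1]])
  if (L < width)
    stop("padded sequence length ", L, " shorter than filter width ", width)
  npos <- L - width + 1
  blocks <- vector("list", length(onehot_list))
  n_win <- integer(length(onehot_list))
  for (i in seq_along(onehot_list)) {
    M <- onehot_list[[i]]
    nz <- which(colSums(M) > 0)
    if (length(nz) == 0) { n_win[i] <- 0L; blocks[[i]] <- NULL; next }
    w0 <- max(1, min(nz) - width + 1)
    w1 <- min(npos, max(nz))
    idx <- w0:w1
    n_win[i] <- length(idx)
    blocks[[i]] <- do.call(cbind, lapply(0:(width - 1), function(k)
      t(M[, idx + k, drop = FALSE])))
  }
  ends <- cumsum(n_win)
  starts <- ends - n_win + 1
  rows_of <- lapply(seq_along(n_win), function(i)
    if (n_win[i] > 0) starts[i]:ends[i] else integer(0))
  list(C = do.call(rbind, blocks[n_win > 0]), npos = npos, A = A,
       n_win = n_win, n_zero = npos - n_win, rows_of = rows_of)
}

build_design <- function(model, features) {
  lapply(model$branches, function(br) {
    if (br$type == "dense") {
      X <- features$counts[[br$feature]]
      if (is.null(X)) stop("unknown dense feature: ", br$feature)
      if (br$apply_log2) X <- log2(1 + X)
      list(X = X)
    } else {
      oh <- features$onehot[[br$feature]]
      if (is.null(oh)) stop("unknown sequence feature: ", br$feature)
      build_conv_bank(oh, br$filter_width)
    }
  })
}

# ---- forward / backward ----------------------------------------------------

relu <- function(x) pmax(x, 0)

# Pooled convolution responses for a gene batch: conv -> max(0, tanh) ->
# sum over windows, with dropped all-zero windows added back analytically.
conv_pool <- function(bank, pr, gi) {
  rows <- unlist(bank$rows_of[gi], use.names = FALSE)
  group <- rep(seq_along(gi), bank$n_win[gi])
  C <- bank$C[rows, , drop = FALSE]
  Z <- C %*% pr$F + matrix(pr$fb, nrow(C), length(pr$fb), byrow = TRUE)
  TH <- tanh(Z)
  H <- relu(TH)
  nf <- length(pr$fb)
  S <- matrix(0, length(gi), nf)
  if (nrow(H) > 0) {
    got <- rowsum(H, group = group)
    S[as.integer(rownames(got)), ] <- got
  }
  th_b <- tanh(pr$fb)
  pad <- outer(bank$n_zero[gi], relu(th_b))
  list(S = S + pad, C = C, TH = TH, group = group, th_b = th_b)
}

model_forward_batch <- function(model, design, gi) {
  n <- length(gi)
  latents <- vector("list", length(model$branches))
  caches <- vector("list", length(model$branches))
  for (j in seq_along(model$branches)) {
    br <- model$branches[[j]]
    pr <- model$params[[j]]
    nrm <- if (!is.null(model$norm)) model$norm[[j]] else NULL
    if (br$type == "dense") {
      Tm <- design[[j]]$X[gi, , drop = FALSE]
      if (!is.null(nrm))
        Tm <- sweep(sweep(Tm, 2, nrm$mu), 2, nrm$sigma, "/")
      cache <- list(T = Tm)
      L <- if (model$combined)
        Tm %*% t(pr$W) + matrix(pr$b, n, length(pr$b), byrow = TRUE)
      else Tm
    } else {
      pool <- conv_pool(design[[j]], pr, gi)
      S <- pool$S
      U <- log2(1 + S)
      Un <- if (!is.null(nrm))
        sweep(sweep(U, 2, nrm$mu), 2, nrm$sigma, "/") else U
      cache <- list(pool = pool, S = S, U = Un,
                    sigma = if (!is.null(nrm)) nrm$sigma else NULL)
      L <- if (model$combined)
        Un %*% t(pr$W) + matrix(pr$b, n, length(pr$b), byrow = TRUE)
      else Un
    }
    latents[[j]] <- L
    caches[[j]] <- cache
  }
  A <- do.call(cbind, latents)
  hid_in <- list()
  for (h in model$head$hidden) {
    hid_in[[length(hid_in) + 1]] <- A
    A <- relu(A %*% t(h$W) + matrix(h$b, n, length(h$b), byrow = TRUE))
  }
  fin <- model$head$final
  out <- A %*% t(fin$W) + matrix(fin$b, n, length(fin$b), byrow = TRUE)
  list(out = out, caches = caches, latents = latents, hid_in = hid_in,
       head_in = A)
}

model_backward_batch <- function(model, design, fwd, gi, dOut) {
  grads <- list(params = vector("list", length(model$params)),
                head = list(hidden = list(), final = NULL))
  fin <- model$head$final
  grads$head$final <- list(W = t(dOut) %*% fwd$head_in, b = colSums(dOut))
  dA <- dOut %*% fin$W
  nh <- length(model$head$hidden)
  if (nh > 0) {
    # output of hidden layer i is the input of layer i+1 (or the head input)
    outs <- c(fwd$hid_in[-1], list(fwd$head_in))
    for (i in rev(seq_len(nh))) {
      h <- model$head$hidden[[i]]
      dA <- dA * (outs[[i]] > 0)
      grads$head$hidden[[i]] <- list(W = t(dA) %*% fwd$hid_in[[i]],
                                     b = colSums(dA))
      dA <- dA %*% h$W
    }
  }
  # split dA across branch latents
  off <- 0
  for (j in seq_along(model$branches)) {
    br <- model$branches[[j]]
    pr <- model$params[[j]]
    cache <- fwd$caches[[j]]
    q <- ncol(fwd$latents[[j]])
    dL <- dA[, (off + 1):(off + q), drop = FALSE]
    off <- off + q
    g <- list()
    if (br$type == "dense") {
      if (model$combined) {
        g$W <- t(dL) %*% cache$T
        g$b <- colSums(dL)
      }
    } else {
      if (model$combined) {
        dU <- dL %*% pr$W
        g$W <- t(dL) %*% cache$U
        g$b <- colSums(dL)
      } else {
        dU <- dL
      }
      if (!is.null(cache$sigma))
        dU <- sweep(dU, 2, cache$sigma, "/")
      dS <- dU / ((1 + cache$S) * log(2))
      pool <- cache$pool
      dHrows <- dS[pool$group, , drop = FALSE]
      dZ <- dHrows * (pool$TH > 0) * (1 - pool$TH^2)
      g$F <- t(pool$C) %*% dZ
      g$fb <- colSums(dZ)
      # dropped all-zero windows: d pad / d fb = gate(tanh(fb)) * (1-tanh^2)
      nz <- design[[j]]$n_zero[gi]
      g$fb <- g$fb + colSums(dS * outer(nz, rep(1, length(pool$th_b)))) *
        (pool$th_b > 0) * (1 - pool$th_b^2)
    }
    grads$params[[j]] <- g
  }
  grads
}

# ---- loss ------------------------------------------------------------------

#' NaN-safe mean squared error
#'
#' Mean of squared prediction errors over mask-true cells only; cells where
#' the mask is FALSE (or either value is `NA`) do not contribute.
#'
#' @param pred,target aligned numeric matrices (or vectors).
#' @param mask logical matrix of the same shape; defaults to cells where both
#'   values are non-missing.
#' @param on_empty behaviour when no cell is valid: `"error"` (default) or
#'   `"zero"` (returns 0 with a warning, used for training batches).
#' @return Scalar loss.
#' @export
nan_safe_mse <- function(pred, target, mask = NULL,
                         on_empty = c("error", "zero")) {
  on_empty <- match.arg(on_empty)
  if (is.null(mask)) mask <- !is.na(pred) & !is.na(target)
  mask <- mask & !is.na(pred) & !is.na(target)
  n <- sum(mask)
  if (n == 0) {
    if (on_empty == "error") stop("nan_safe_mse: no valid cells")
    warning("nan_safe_mse: batch has no valid cells; contributing zero loss")
    return(0)
  }
  sum((pred[mask] - target[mask])^2) / n
}

#' Predict log2 protein abundance from PTR parameters
#'
#' Implements `log2(iBAQ) = a * log2(TPM) + b + <delta, log2(context TPM)>`.
#'
#' @param params list or data.frame row with elements `a`, `b` and optional
#'   `delta` (numeric vector).
#' @param log2_tpm transcript abundance (scalar or vector over tissues).
#' @param context_log2_tpm matrix (length(delta) x tissues) or vector of
#'   context-gene transcript abundances; required when `delta` is non-empty.
#' @return Predicted log2 iBAQ, `NA` where `log2_tpm` is missing.
#' @export
predict_log2_ibaq <- function(params, log2_tpm, context_log2_tpm = NULL) {
  delta <- params$delta
  out <- params$a * log2_tpm + params$b
  if (!is.null(delta) && length(delta) > 0) {
    ctx <- if (is.matrix(context_log2_tpm)) context_log2_tpm
           else if (length(context_log2_tpm) == length(delta))
             matrix(context_log2_tpm, ncol = 1)
           else rbind(context_log2_tpm)
    if (nrow(ctx) != length(delta))
      stop("context vector length does not match delta")
    out <- out + as.vector(crossprod(matrix(delta, ncol = 1), ctx))
  }
  out
}

# ---- training --------------------------------------------------------------

context_matrix <- function(dataset, context_genes) {
  if (is.null(context_genes) || length(context_genes) == 0) return(NULL)
  idx <- match(context_genes, dataset$gene_ids)
  if (anyNA(idx)) stop("context genes absent from dataset: ",
                       paste(context_genes[is.na(idx)], collapse = ", "))
  dataset$log2_tpm[idx, , drop = FALSE]
}

# The head is optimized against tissue-centred transcript abundance
# (x - x_center, and centred context abundances): centring removes the
# strong coupling between the gradient and offset outputs and leaves the
# fitted function unchanged -- the reported offset is recovered exactly as
# b = b_internal - a * x_center - <delta, ctx_center>.
batch_loss_grad <- function(out, x, y, valid) {
  n_out <- ncol(out)
  a <- out[, 1]; b <- out[, 2]
  x0 <- x; x0[!valid] <- 0
  y0 <- y; y0[!valid] <- 0
  pred <- x0 * a + b
  if (n_out > 2) {
    delta <- out[, 3:n_out, drop = FALSE]
    ctx <- attr(valid, "ctx0")
    pred <- pred + delta %*% ctx
  }
  E <- (pred - y0)
  E[!valid] <- 0
  N <- sum(valid)
  if (N == 0) return(NULL)
  loss <- sum(E^2)
  dPred <- 2 * E / N
  dOut <- cbind(rowSums(dPred * x0), rowSums(dPred))
  if (n_out > 2) dOut <- cbind(dOut, dPred %*% t(attr(valid, "ctx0")))
  list(loss = loss, n = N, dOut = dOut)
}

sgd_update <- function(model, grads, lr) {
  for (j in seq_along(model$params)) {
    for (nm in names(grads$params[[j]]))
      model$params[[j]][[nm]] <- model$params[[j]][[nm]] - lr * grads$params[[j]][[nm]]
  }
  for (i in seq_along(grads$head$hidden)) {
    model$head$hidden[[i]]$W <- model$head$hidden[[i]]$W - lr * grads$head$hidden[[i]]$W
    model$head$hidden[[i]]$b <- model$head$hidden[[i]]$b - lr * grads$head$hidden[[i]]$b
  }
  model$head$final$W <- model$head$final$W - lr * grads$head$final$W
  model$head$final$b <- model$head$final$b - lr * grads$head$final$b
  model
}

#' Train a PTR model with SGD
#'
#' Minimizes the NaN-safe MSE over all valid (gene, tissue) cells of the
#' training genes.  One gene is one sample (its loss spans all its valid
#' tissues); batches hold 32 genes by default; the optimizer is plain
#' stochastic gradient descent without momentum.  Deterministic given the
#' seed.
#'
#' @param model a [ptr_model()].
#' @param dataset a [ptr_dataset].
#' @param features a `ptr_features` object covering the training genes.
#' @param genes gene IDs to train on (default: all genes shared by dataset
#'   and features).
#' @param context_genes gene IDs whose log2 TPM enters the delta term; length
#'   must equal the model's `n_context_genes`.
#' @param lr learning rate (defaults per feature type are in
#'   [default_config()]).
#' @param epochs number of epochs.
#' @param batch_size genes per batch (default 32).
#' @param seed RNG seed controlling batch shuffling.
#' @param tissue_subset optional tissue IDs; cells outside are excluded from
#'   training (used for tissue-axis cross-validation).
#' @return The fitted model, with a `loss_trace` attribute (per-epoch
#'   training loss).
#' @export
train_ptr_model <- function(model, dataset, features, genes = NULL,
                            context_genes = NULL, lr = 1e-3, epochs = 256,
                            batch_size = 32, seed = 1, tissue_subset = NULL) {
  stopifnot(lr > 0)
  if (is.null(genes))
    genes <- intersect(dataset$gene_ids, features$gene_ids)
  frow <- match(genes, features$gene_ids)
  drow <- match(genes, dataset$gene_ids)
  if (anyNA(frow) || anyNA(drow)) stop("genes missing from dataset or features")
  k <- model$n_context_genes
  if (k != length(context_genes %||% character(0)))
    stop("context_genes length must equal the model's n_context_genes")
  ctx <- context_matrix(dataset, context_genes)
  design <- build_design(model, features)
  x_all <- dataset$log2_tpm[drow, , drop = FALSE]
  y_all <- dataset$log2_ibaq[drow, , drop = FALSE]
  v_all <- dataset$valid_mask[drow, , drop = FALSE]
  if (!is.null(tissue_subset))
    v_all[, !(dataset$tissue_ids %in% tissue_subset)] <- FALSE
  if (!is.null(ctx)) {
    ctx0 <- ctx; ctx0[is.na(ctx0)] <- 0
    v_all <- v_all & matrix(rep(colSums(is.na(ctx)) == 0, each = nrow(v_all)),
                            nrow(v_all))
  }
  if (sum(v_all) == 0) stop("no valid training cells")
  if (is.null(model$norm))
    model$norm <- compute_branch_norm(model, design, frow)
  if (is.null(model$x_center)) {
    model$x_center <- mean(x_all[v_all])
    model$ctx_center <- if (!is.null(ctx)) rowMeans(ctx, na.rm = TRUE)
                        else numeric(0)
  }
  x_all <- x_all - model$x_center
  if (!is.null(ctx)) ctx0 <- ctx0 - model$ctx_center
  n <- length(genes)
  loss_trace <- numeric(epochs)
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_n <- 0
    for (start in seq(1, n, by = batch_size)) {
      bi <- ord[start:min(start + batch_size - 1, n)]
      valid <- v_all[bi, , drop = FALSE]
      if (!is.null(ctx)) attr(valid, "ctx0") <- ctx0
      fwd <- model_forward_batch(model, design, frow[bi])
      lg <- batch_loss_grad(fwd$out, x_all[bi, , drop = FALSE],
                            y_all[bi, , drop = FALSE], valid)
      if (is.null(lg)) next
      if (!is.finite(lg$loss))
        stop("non-finite loss at epoch ", ep, "; lower the learning rate")
      grads <- model_backward_batch(model, design, fwd, frow[bi], lg$dOut)
      model <- sgd_update(model, grads, lr)
      ep_loss <- ep_loss + lg$loss
      ep_n <- ep_n + lg$n
    }
    loss_trace[ep] <- ep_loss / max(ep_n, 1)
  }
  attr(model, "loss_trace") <- loss_trace
  attr(model, "train_genes") <- genes
  attr(model, "context_genes") <- context_genes
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-gene PTR parameters from a (fitted) model
#'
#' Runs the forward pass for the requested genes and returns the head
#' outputs mapped to (a, b, delta).
#'
#' @param model a [ptr_model], typically fitted.
#' @param features a `ptr_features` object.
#' @param genes gene IDs (default: all in `features`).
#' @return data.frame with columns `gene_id`, `a`, `b` and `delta.1..k`.
#' @export
ptr_parameters <- function(model, features, genes = NULL) {
  if (is.null(genes)) genes <- features$gene_ids
  gi <- match(genes, features$gene_ids)
  if (anyNA(gi)) stop("genes missing from features")
  design <- build_design(model, features)
  out <- model_forward_batch(model, design, gi)$out
  b <- out[, 2]
  k <- model$n_context_genes
  # undo the internal centring reparameterization (see batch_loss_grad)
  if (!is.null(model$x_center)) b <- b - out[, 1] * model$x_center
  if (k > 0 && length(model$ctx_center %||% numeric(0)) == k)
    b <- b - out[, 3:(2 + k), drop = FALSE] %*% model$ctx_center
  df <- data.frame(gene_id = genes, a = out[, 1], b = as.vector(b),
                   stringsAsFactors = FALSE)
  if (k > 0) {
    d <- out[, 3:(2 + k), drop = FALSE]
    colnames(d) <- paste0("delta.", seq_len(k))
    df <- cbind(df, d)
  }
  df
}

#' Predict the full log2 iBAQ matrix for a set of genes
#'
#' @inheritParams ptr_parameters
#' @param dataset a [ptr_dataset] supplying log2 TPM (and context TPM).
#' @param context_genes context-gene IDs (length = model's n_context_genes).
#' @return genes x tissues matrix of predictions; `NA` where log2 TPM (or a
#'   context value) is missing.
#' @export
predict_ptr_matrix <- function(model, dataset, features, genes = NULL,
                               context_genes = NULL) {
  if (is.null(genes)) genes <- intersect(dataset$gene_ids, features$gene_ids)
  pars <- ptr_parameters(model, features, genes)
  x <- dataset$log2_tpm[match(genes, dataset$gene_ids), , drop = FALSE]
  pred <- x * pars$a + pars$b
  k <- model$n_context_genes
  if (k > 0) {
    ctx <- context_matrix(dataset, context_genes)
    pred <- pred + as.matrix(pars[, paste0("delta.", seq_len(k))]) %*% ctx
    pred[, colSums(is.na(ctx)) > 0] <- NA
  }
  rownames(pred) <- genes
  pred
}

# ---- scoring ---------------------------------------------------------------

#' Per-gene coefficient of determination
#'
#' For each gene, r2 = 1 - SS_res / SS_tot over its valid tissues, where
#' SS_tot is taken against the gene's own mean target value, so a model that
#' predicts each gene's average protein level scores exactly 0.  Genes with
#' fewer than 2 valid cells or zero target variance are excluded and counted.
#'
#' @param pred,target genes x tissues matrices.
#' @param mask logical validity matrix.
#' @return List with `scores` (named per-gene r2, `NA` where undefined),
#'   `mean` (unweighted mean over defined scores) and `n_undefined`.
#' @export
r2_per_gene <- function(pred, target, mask = NULL) {
  if (is.null(mask)) mask <- !is.na(target)
  mask <- mask & !is.na(pred) & !is.na(target)
  n_genes <- nrow(target)
  scores <- rep(NA_real_, n_genes)
  names(scores) <- rownames(target)
  for (g in seq_len(n_genes)) {
    v <- mask[g, ]
    if (sum(v) < 2) next
    y <- target[g, v]; yh <- pred[g, v]
    sst <- sum((y - mean(y))^2)
    if (sst == 0) next
    scores[g] <- 1 - sum((y - yh)^2) / sst
  }
  list(scores = scores, mean = mean(scores, na.rm = TRUE),
       n_undefined = sum(is.na(scores)))
}

# ---- cross-validation ------------------------------------------------------

#' Repeated k-fold cross-validation of a PTR model
#'
#' Five independent repeats of tenfold cross-validation by default.  With
#' `split_axis = "genes"` (model experiments) folds partition the genes and
#' each fold's model is scored on unseen genes over all their valid tissues.
#' With `split_axis = "tissues"` (baseline experiments) folds partition the
#' tissues and fitted models are scored per gene on unseen tissues.
#'
#' @param dataset a [ptr_dataset].
#' @param features a `ptr_features` object.
#' @param branches branch specification list (see [ptr_model()]).
#' @param genes gene IDs entering the CV (default: all shared genes).
#' @param n_repeats,n_folds repetition and fold counts.
#' @param split_axis `"genes"` or `"tissues"`.
#' @param lr,epochs,batch_size training hyperparameters.
#' @param n_context_genes,context_genes delta-extension inputs.
#' @param combine_widths combine-layer widths (see [ptr_model()]).
#' @param seed master seed; per-repeat/per-fold seeds are derived from it.
#' @param keep_models return the fitted models (default TRUE; needed for
#'   motif extraction).
#' @return List of class `ptr_cv` with a `scores` data.frame (one row per
#'   repeat x fold: mean r2, n scored genes), `gene_scores` (per-gene r2
#'   pooled over folds), summary `mean`/`sd`, and optionally `models`.
#' @export
cross_validate <- function(dataset, features, branches, genes = NULL,
                           n_repeats = 5, n_folds = 10,
                           split_axis = c("genes", "tissues"),
                           lr = 1e-3, epochs = 256, batch_size = 32,
                           n_context_genes = 0, context_genes = NULL,
                           combine_widths = NULL, seed = 1,
                           keep_models = TRUE, conv_init_scale = 1 / 3,
                           conv_init_bias = 0) {
  split_axis <- match.arg(split_axis)
  if (is.null(genes)) genes <- intersect(dataset$gene_ids, features$gene_ids)
  items <- if (split_axis == "genes") genes else dataset$tissue_ids
  if (length(items) < n_folds)
    stop("fewer items (", length(items), ") than folds (", n_folds, ")")
  rows <- list(); models <- list()
  gene_scores <- list()
  for (r in seq_len(n_repeats)) {
    fold_seed <- child_seed(seed, r)
    set.seed(fold_seed)
    fold_of <- sample(rep(seq_len(n_folds), length.out = length(items)))
    for (f in seq_len(n_folds)) {
      test_items <- items[fold_of == f]
      train_items <- items[fold_of != f]
      run_seed <- child_seed(seed, r * 1000 + f)
      if (split_axis == "genes") {
        model <- ptr_model(branches, features, n_context_genes,
                           combine_widths, seed = run_seed,
                           conv_init_scale = conv_init_scale,
                           conv_init_bias = conv_init_bias)
        model <- train_ptr_model(model, dataset, features, genes = train_items,
                                 context_genes = context_genes, lr = lr,
                                 epochs = epochs, batch_size = batch_size,
                                 seed = run_seed)
        pred <- predict_ptr_matrix(model, dataset, features, test_items,
                                   context_genes)
        sc <- r2_per_gene(pred, dataset$log2_ibaq[match(test_items, dataset$gene_ids), , drop = FALSE],
                          dataset$valid_mask[match(test_items, dataset$gene_ids), , drop = FALSE])
      } else {
        model <- ptr_model(branches, features, n_context_genes,
                           combine_widths, seed = run_seed,
                           conv_init_scale = conv_init_scale,
                           conv_init_bias = conv_init_bias)
        model <- train_ptr_model(model, dataset, features, genes = genes,
                                 context_genes = context_genes, lr = lr,
                                 epochs = epochs, batch_size = batch_size,
                                 seed = run_seed, tissue_subset = train_items)
        pred <- predict_ptr_matrix(model, dataset, features, genes,
                                   context_genes)
        gi <- match(genes, dataset$gene_ids)
        tcols <- dataset$tissue_ids %in% test_items
        sc <- r2_per_gene(pred[, tcols, drop = FALSE],
                          dataset$log2_ibaq[gi, tcols, drop = FALSE],
                          dataset$valid_mask[gi, tcols, drop = FALSE])
      }
      rows[[length(rows) + 1]] <- data.frame(
        repeat_id = r, fold = f, mean_r2 = sc$mean,
        n_scored = sum(!is.na(sc$scores)), n_undefined = sc$n_undefined)
      gene_scores[[length(gene_scores) + 1]] <- sc$scores
      if (keep_models) models[[length(models) + 1]] <-
        structure(model, repeat_id = r, fold = f)
    }
  }
  scores <- do.call(rbind, rows)
  structure(list(scores = scores,
                 mean = mean(scores$mean_r2, na.rm = TRUE),
                 sd = stats::sd(scores$mean_r2),
                 gene_scores = gene_scores,
                 models = if (keep_models) models else NULL,
                 split_axis = split_axis),
            class = "ptr_cv")
}

#' @export
print.ptr_cv <- function(x, ...) {
  cat(sprintf("ptr_cv (%s folds): %d runs, mean r2 = %.3f +/- %.3f\n",
              x$split_axis, nrow(x$scores), x$mean, x$sd))
  invisible(x)
}

# Deterministic fan-out of a master seed into per-task sub-seeds.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 77777 * as.numeric(i)) %% 2147483647)
}

# ---- standalone branch forwards (useful for testing/inspection) ------------

#' Convolutional branch forward pass on a single one-hot matrix
#'
#' conv -> max(0, tanh) -> sum-pool over positions -> log2(1 + s).
#'
#' @param onehot alphabet x L one-hot matrix (all-zero padding columns are
#'   allowed and contribute like any other window content).
#' @param filters (alphabet * width) x n_filters weight matrix, columns are
#'   `as.vector()`-flattened alphabet x width filters.
#' @param bias per-filter bias (default 0).
#' @param width filter width in positions.
#' @return Length-n_filters pooled output vector.
#' @export
conv_branch_forward <- function(onehot, filters, bias = 0, width) {
  if (ncol(onehot) < width) stop("sequence shorter than filter width")
  bias <- rep(bias, length.out = ncol(filters))
  bank <- build_conv_bank(list(onehot), width)
  S <- if (is.null(bank$C)) rep(0, ncol(filters)) else {
    Z <- bank$C %*% filters +
      matrix(bias, nrow(bank$C), ncol(filters), byrow = TRUE)
    colSums(relu(tanh(Z)))
  }
  log2(1 + S + bank$n_zero[1] * relu(tanh(bias)))
}

#' Dense branch forward pass on a single feature vector
#'
#' @param v feature vector.
#' @param W,b affine weights (rows = outputs) and bias.
#' @param apply_log2 apply log2(1 + v) before the affine map.
#' @return Output vector.
#' @export
dense_branch_forward <- function(v, W, b = 0, apply_log2 = TRUE) {
  if (ncol(W) != length(v)) stop("feature vector length does not match weights")
  if (apply_log2) v <- log2(1 + v)
  as.vector(W %*% v + b)
}
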