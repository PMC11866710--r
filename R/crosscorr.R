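# Gene-gene cross-correlation screen: cross-validated linear-regression MSE
# for every (input-gene mRNA -> target-gene protein) pair, degree
# distribution of top correlates, and top-k context-gene selection.

#' Pairwise gene-gene regression MSE matrix
#'
#' For every (input h, target g) pair, fits `log2 iBAQ_g ~ log2 TPM_h` on
#' training tissues and records the held-out MSE, over `n_repeats`
#' independent repeats of `n_folds`-fold cross-validation on tissues; the
#' MSE values are averaged across all repeats and folds.  Pairs sharing
#' fewer than `min_points` tissues with both values valid are `NA`.
#'
#' @param dataset a [ptr_dataset].
#' @param input_genes,target_genes gene-ID subsets (default: all genes);
#'   large all-pairs runs should be chunked over `input_genes`.
#' @param n_repeats,n_folds CV structure (default 5 x 10).
#' @param min_points minimum shared valid tissues (default 21).
#' @param seed RNG seed for fold assignment.
#' @param permute_inputs permute each input gene's tissue labels before
#'   fitting (the randomized control); permutation is seeded.
#' @return Object of class `crosscorr_matrix`: list with `mean_mse`
#'   (inputs x targets, `NA` where undefined), `mean_r2` (same layout,
#'   held-out r2 averaged the same way), `n_shared` and the ID vectors.
#' @export
pairwise_gene_regression <- function(dataset, input_genes = NULL,
                                     target_genes = NULL, n_repeats = 5,
                                     n_folds = 10, min_points = 21, seed = 1,
                                     permute_inputs = FALSE) {
  if (is.null(input_genes)) input_genes <- dataset$gene_ids
  if (is.null(target_genes)) target_genes <- dataset$gene_ids
  n_t <- length(dataset$tissue_ids)
  if (n_t < n_folds) stop("fewer tissues than folds")
  hi <- match(input_genes, dataset$gene_ids)
  gi <- match(target_genes, dataset$gene_ids)
  if (anyNA(hi) || anyNA(gi)) stop("unknown gene IDs")
  X <- dataset$log2_tpm[hi, , drop = FALSE]       # inputs x tissues
  Y <- dataset$log2_ibaq[gi, , drop = FALSE]      # targets x tissues
  if (permute_inputs) {
    set.seed(child_seed(seed, 999983))
    for (i in seq_len(nrow(X))) X[i, ] <- X[i, sample.int(n_t)]
  }
  Xv <- !is.na(X); Yv <- !is.na(Y)
  n_shared <- Xv %*% t(Yv * 1)                     # inputs x targets
  X0 <- X; X0[!Xv] <- 0
  Y0 <- Y; Y0[!Yv] <- 0
  tY0 <- t(Y0); tYv <- t(Yv)
  mse_sum <- matrix(0, nrow(X), nrow(Y))
  r2_sum <- matrix(0, nrow(X), nrow(Y))
  n_runs <- matrix(0L, nrow(X), nrow(Y))
  for (r in seq_len(n_repeats)) {
    set.seed(child_seed(seed, r))
    fold_of <- sample(rep(seq_len(n_folds), length.out = n_t))
    for (f in seq_len(n_folds)) {
      tr <- fold_of != f
      for (h in seq_len(nrow(X))) {
        x <- X0[h, ]; xv <- Xv[h, ]
        # per-target masked OLS sums on training tissues
        vtr <- tYv * (xv & tr)                   # tissues x targets
        n <- colSums(vtr)
        sx <- colSums(x * vtr)
        sy <- colSums(tY0 * vtr)
        sxx <- colSums(x^2 * vtr)
        sxy <- colSums(x * tY0 * vtr)
        denom <- n * sxx - sx^2
        ok_fit <- n >= 2 & denom > 0
        a <- ifelse(ok_fit, (n * sxy - sx * sy) / denom, NA_real_)
        b <- ifelse(ok_fit, (sy - a * sx) / n, NA_real_)
        # held-out error
        vte <- tYv * (xv & !tr)
        m <- colSums(vte)
        pred_err2 <- colSums((outer(x, a) + matrix(b, n_t, length(b),
                                                   byrow = TRUE) - tY0)^2 * vte)
        mse <- ifelse(ok_fit & m > 0, pred_err2 / m, NA_real_)
        ybar <- ifelse(m > 0, colSums(tY0 * vte) / m, NA_real_)
        sst <- colSums((tY0 - matrix(ybar, n_t, length(ybar),
                                     byrow = TRUE))^2 * vte)
        r2 <- ifelse(ok_fit & m >= 2 & sst > 0, 1 - pred_err2 / sst, NA_real_)
        got <- !is.na(mse)
        mse_sum[h, got] <- mse_sum[h, got] + mse[got]
        n_runs[h, got] <- n_runs[h, got] + 1L
        got2 <- !is.na(r2)
        r2_sum[h, got2] <- r2_sum[h, got2] + r2[got2]
      }
    }
  }
  mean_mse <- ifelse(n_runs > 0, mse_sum / n_runs, NA_real_)
  mean_r2 <- ifelse(n_runs > 0, r2_sum / n_runs, NA_real_)
  low <- n_shared < min_points
  mean_mse[low] <- NA_real_
  mean_r2[low] <- NA_real_
  dimnames(mean_mse) <- dimnames(mean_r2) <- dimnames(n_shared) <-
    list(input_genes, target_genes)
  structure(list(input_gene_ids = input_genes, target_gene_ids = target_genes,
                 mean_mse = mean_mse, mean_r2 = mean_r2, n_shared = n_shared),
            class = "crosscorr_matrix")
}

#' Degree of each input gene as a top correlate
#'
#' For every target gene, the input gene with the minimum mean MSE (NaN-safe
#' argmin; ties broken by lexicographically smallest input-gene ID) is its
#' top correlate; an input gene's degree is the number of targets for which
#' it wins.  Targets whose column is all-missing are skipped and counted.
#'
#' @param mat a `crosscorr_matrix`.
#' @return List with `degrees` (named integer vector over input genes),
#'   `top_input` (named character: winner per scored target) and
#'   `n_skipped_targets`.
#' @export
top_correlate_degrees <- function(mat) {
  M <- mat$mean_mse
  ord <- order(mat$input_gene_ids)        # lexicographic tie-break
  degrees <- stats::setNames(integer(length(mat$input_gene_ids)),
                             mat$input_gene_ids)
  top <- character(0)
  skipped <- 0L
  for (g in seq_along(mat$target_gene_ids)) {
    col <- M[ord, g]
    if (all(is.na(col))) { skipped <- skipped + 1L; next }
    w <- mat$input_gene_ids[ord][which.min(col)]
    degrees[w] <- degrees[w] + 1L
    top[mat$target_gene_ids[g]] <- w
  }
  list(degrees = degrees, top_input = top, n_skipped_targets = skipped)
}

#' Select the top-k context genes by degree
#'
#' @param degrees named degree vector from [top_correlate_degrees()].
#' @param k number of context genes (the study screens 10, 20 and 40).
#' @return Character vector of the k highest-degree input-gene IDs (ties
#'   broken by gene ID); shorter, with a warning, when fewer than k genes
#'   have positive degree.
#' @export
select_top_k <- function(degrees, k) {
  pos <- degrees[degrees > 0]
  pos <- pos[order(-pos, names(pos))]
  if (length(pos) < k) {
    warning("only ", length(pos), " genes with positive degree; returning all")
    return(names(pos))
  }
  names(pos)[seq_len(k)]
}

#' Write a crosscorr matrix as TSV
#'
#' @param mat a `crosscorr_matrix`.
#' @param path output path.
#' @export
write_crosscorr_tsv <- function(mat, path) {
  write_expression_tsv(mat$mean_mse, path, id_col = "input_gene")
}
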