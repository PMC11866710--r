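# Per-gene regression baselines: ordinary least squares of log2 iBAQ on log2
# TPM across tissues, gradient/fit-quality classification, the naive
# transcript-scaling predictor, and abundance-variance summaries.

#' Per-gene ordinary least-squares fit
#'
#' Fits `log2(iBAQ) = a * log2(TPM) + b` over the valid tissue pairs of one
#' gene.  r2 is in-sample, against the gene's mean log2 iBAQ.
#'
#' @param log2_tpm,log2_ibaq numeric vectors over tissues.
#' @param mask logical validity vector (default: both values non-missing).
#' @param gene_id optional identifier carried into the result.
#' @return List of class `linear_fit` with `gene_id`, `a`, `b`, `r2`,
#'   `n_points`.  With fewer than 2 valid pairs or zero TPM variance the fit
#'   is undefined (`a`/`b`/`r2` are `NA`) and `flag` states why; with zero
#'   iBAQ variance `a` and `b` are defined but `r2` is `NA`.
#' @export
per_gene_linear_fit <- function(log2_tpm, log2_ibaq, mask = NULL,
                                gene_id = NA_character_) {
  if (is.null(mask)) mask <- !is.na(log2_tpm) & !is.na(log2_ibaq)
  mask <- mask & !is.na(log2_tpm) & !is.na(log2_ibaq)
  x <- log2_tpm[mask]; y <- log2_ibaq[mask]
  n <- length(x)
  out <- list(gene_id = gene_id, a = NA_real_, b = NA_real_, r2 = NA_real_,
              n_points = n, flag = NA_character_)
  class(out) <- "linear_fit"
  if (n < 2) { out$flag <- "too_few_points"; return(out) }
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) { out$flag <- "zero_tpm_variance"; return(out) }
  a <- sum((x - mean(x)) * (y - mean(y))) / sxx
  b <- mean(y) - a * mean(x)
  sst <- sum((y - mean(y))^2)
  out$a <- a; out$b <- b
  if (sst == 0) { out$flag <- "zero_ibaq_variance"; return(out) }
  out$r2 <- 1 - sum((y - (a * x + b))^2) / sst
  out
}

#' Linear fits for every gene of a dataset
#'
#' @param dataset a [ptr_dataset].
#' @param min_points minimum valid pairs for a fit to be attempted.
#' @return data.frame with one row per gene: `gene_id`, `a`, `b`, `r2`,
#'   `n_points`, `flag`.
#' @export
fit_all_genes <- function(dataset, min_points = 2) {
  res <- lapply(seq_along(dataset$gene_ids), function(g) {
    f <- per_gene_linear_fit(dataset$log2_tpm[g, ], dataset$log2_ibaq[g, ],
                             dataset$valid_mask[g, ], dataset$gene_ids[g])
    data.frame(gene_id = f$gene_id, a = f$a, b = f$b, r2 = f$r2,
               n_points = f$n_points,
               flag = ifelse(is.na(f$flag), "", f$flag),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, res)
  df$flag[df$n_points < min_points & df$flag == ""] <- "too_few_points"
  df
}

#' Cross-validated comparison of per-gene regression families
#'
#' For each gene, fits a polynomial regression of log2 iBAQ on log2 TPM on
#' training tissues and scores r2 on held-out tissues (reference: the mean of
#' the held-out targets), using repeated k-fold cross-validation over
#' tissues.
#'
#' @param dataset a [ptr_dataset].
#' @param families named integer vector of polynomial degrees, default
#'   `c(linear = 1, quadratic = 2)`.
#' @param n_repeats,n_folds CV structure (default 5 x 10).
#' @param min_train minimum training pairs per gene and fold.
#' @param seed RNG seed for fold assignment.
#' @return data.frame with one row per family: mean, median and sd of
#'   per-gene held-out r2 (the median is the robust summary; per-gene r2 on
#'   small held-out tissue sets has a heavy negative tail).
#' @export
regressor_comparison <- function(dataset, families = c(linear = 1, quadratic = 2),
                                 n_repeats = 5, n_folds = 10, min_train = 3,
                                 seed = 1) {
  tissues <- dataset$tissue_ids
  n_t <- length(tissues)
  if (n_t < n_folds) stop("fewer tissues than folds")
  res <- lapply(names(families), function(fam) {
    deg <- families[[fam]]
    scores <- c()
    for (r in seq_len(n_repeats)) {
      set.seed(child_seed(seed, r))
      fold_of <- sample(rep(seq_len(n_folds), length.out = n_t))
      for (f in seq_len(n_folds)) {
        train_t <- fold_of != f
        for (g in seq_along(dataset$gene_ids)) {
          v <- dataset$valid_mask[g, ]
          tr <- v & train_t; te <- v & !train_t
          if (sum(tr) < max(min_train, deg + 1) || sum(te) < 2) next
          x <- dataset$log2_tpm[g, ]; y <- dataset$log2_ibaq[g, ]
          dm <- function(xx) cbind(1, outer(xx, seq_len(deg), `^`))
          cf <- stats::lm.fit(dm(x[tr]), y[tr])$coefficients
          cf[is.na(cf)] <- 0
          yh <- as.vector(dm(x[te]) %*% cf)
          sst <- sum((y[te] - mean(y[te]))^2)
          if (sst == 0) next
          scores <- c(scores, 1 - sum((y[te] - yh)^2) / sst)
        }
      }
    }
    data.frame(family = fam, mean_r2 = mean(scores),
               median_r2 = stats::median(scores), sd_r2 = stats::sd(scores),
               n_scores = length(scores), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Naive transcript-scaling predictor
#'
#' `iBAQ_SPEC = iBAQ_AVG * TPM_SPEC / TPM_AVG`, with every quantity on the
#' log2 scale: the tissue-specific protein level is taken as the gene's
#' average protein level rescaled by the ratio of tissue-specific to average
#' transcript level.
#'
#' @param ibaq_avg gene's average log2 iBAQ.
#' @param tpm_spec tissue-specific log2 TPM (scalar or vector).
#' @param tpm_avg gene's average log2 TPM; a zero average yields `NA`.
#' @return Predicted tissue-specific log2 iBAQ.
#' @export
naive_scaling_predict <- function(ibaq_avg, tpm_spec, tpm_avg) {
  out <- ibaq_avg * tpm_spec / tpm_avg
  out[tpm_avg == 0] <- NA_real_
  out
}

#' Evaluate the naive scaling predictor on a dataset
#'
#' Per-gene averages are computed over valid cells; the predictor is scored
#' with [r2_per_gene()].
#'
#' @param dataset a [ptr_dataset].
#' @return List with per-gene `scores` and their `mean`.
#' @export
naive_scaling_r2 <- function(dataset) {
  x <- dataset$log2_tpm; y <- dataset$log2_ibaq
  x[!dataset$valid_mask] <- NA; y[!dataset$valid_mask] <- NA
  tpm_avg <- rowMeans(x, na.rm = TRUE)
  ibaq_avg <- rowMeans(y, na.rm = TRUE)
  pred <- naive_scaling_predict(ibaq_avg, x, tpm_avg)
  sc <- r2_per_gene(pred, y, dataset$valid_mask)
  list(scores = sc$scores, mean = sc$mean)
}

#' Classify per-gene fits by gradient and fit quality
#'
#' Labels each fit good (`r2 >= r2_cut`) or poor, bins the gradients, and
#' exports the negative-gradient robust-fit gene list
#' (`a < neg_gradient_cut` and `r2 >= r2_cut`).
#'
#' @param fits data.frame from [fit_all_genes()].
#' @param r2_cut good/poor threshold (default 0.7, inclusive for good).
#' @param neg_gradient_cut gradient threshold for the export (default -0.2,
#'   strict).
#' @param bins gradient bin edges; default width-0.2 bins over [-1, 1.4] with
#'   open outer bins.
#' @return List with `table` (bin x quality count matrix), `labels`
#'   (per-gene data.frame with `quality` and `bin`), and
#'   `negative_robust_genes`.
#' @export
classify_fits <- function(fits, r2_cut = 0.7, neg_gradient_cut = -0.2,
                          bins = seq(-1, 1.4, by = 0.2)) {
  ok <- !is.na(fits$r2) & !is.na(fits$a)
  fits <- fits[ok, , drop = FALSE]
  quality <- ifelse(fits$r2 >= r2_cut, "good", "poor")
  edges <- c(-Inf, bins, Inf)
  bin <- cut(fits$a, breaks = edges, right = FALSE)
  tab <- table(bin = bin, quality = factor(quality, c("good", "poor")))
  neg <- fits$gene_id[fits$a < neg_gradient_cut & fits$r2 >= r2_cut]
  list(table = tab,
       labels = data.frame(gene_id = fits$gene_id, quality = quality,
                           bin = as.character(bin), stringsAsFactors = FALSE),
       negative_robust_genes = neg)
}

#' Per-gene abundance and variance summary
#'
#' Mean log2 TPM, variance of log2 TPM and variance of log2 iBAQ over the
#' valid cells of each gene (sample variance, n - 1 denominator).
#'
#' @param dataset a [ptr_dataset].
#' @param min_points minimum valid cells (default 2).
#' @return data.frame: `gene_id`, `mean_log2_tpm`, `var_log2_tpm`,
#'   `var_log2_ibaq`, `n_points`.
#' @export
abundance_variance_summary <- function(dataset, min_points = 2) {
  res <- lapply(seq_along(dataset$gene_ids), function(g) {
    v <- dataset$valid_mask[g, ]
    n <- sum(v)
    if (n < min_points) return(NULL)
    x <- dataset$log2_tpm[g, v]; y <- dataset$log2_ibaq[g, v]
    data.frame(gene_id = dataset$gene_ids[g], mean_log2_tpm = mean(x),
               var_log2_tpm = stats::var(x), var_log2_ibaq = stats::var(y),
               n_points = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Compare variance distributions between two datasets
#'
#' Two-sided Mann-Whitney U test on per-gene variances of either the
#' transcript or the protein abundance.
#'
#' @param summary_a,summary_b outputs of [abundance_variance_summary()].
#' @param what `"tpm"` or `"ibaq"`.
#' @return The `htest` object from [stats::wilcox.test()].
#' @export
compare_variances <- function(summary_a, summary_b, what = c("tpm", "ibaq")) {
  what <- match.arg(what)
  col <- if (what == "tpm") "var_log2_tpm" else "var_log2_ibaq"
  stats::wilcox.test(summary_a[[col]], summary_b[[col]], exact = FALSE)
}
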