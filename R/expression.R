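#' Matched transcript/protein expression dataset
#'
#' Container for a pair of aligned genes x tissues abundance matrices on the
#' log2 scale (transcript abundance as log2 TPM, protein abundance as log2
#' iBAQ), together with an explicit validity mask.  A cell is valid only when
#' both measurements are present and passed their detection thresholds;
#' non-valid cells are stored as `NA` in the matrices and `FALSE` in the mask.
#'
#' @param log2_tpm genes x tissues numeric matrix of log2 TPM; `NA` = missing.
#' @param log2_ibaq genes x tissues numeric matrix of log2 iBAQ; `NA` = missing.
#' @param gene_ids,tissue_ids optional identifier vectors; default to the
#'   dimnames of `log2_tpm`.
#' @return An object of class `ptr_dataset` with elements `gene_ids`,
#'   `tissue_ids`, `log2_tpm`, `log2_ibaq` and `valid_mask`.
#' @export
ptr_dataset <- function(log2_tpm, log2_ibaq, gene_ids = rownames(log2_tpm),
                        tissue_ids = colnames(log2_tpm)) {
  if (!all(dim(log2_tpm) == dim(log2_ibaq)))
    stop("log2_tpm and log2_ibaq must have identical dimensions")
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(log2_tpm)))
  if (is.null(tissue_ids)) tissue_ids <- paste0("t", seq_len(ncol(log2_tpm)))
  dimnames(log2_tpm) <- dimnames(log2_ibaq) <- list(gene_ids, tissue_ids)
  structure(list(
    gene_ids   = gene_ids,
    tissue_ids = tissue_ids,
    log2_tpm   = log2_tpm,
    log2_ibaq  = log2_ibaq,
    valid_mask = !is.na(log2_tpm) & !is.na(log2_ibaq)
  ), class = "ptr_dataset")
}

#' @export
print.ptr_dataset <- function(x, ...) {
  cat(sprintf("ptr_dataset: %d genes x %d tissues, %d valid cells (%.1f%%)\n",
              length(x$gene_ids), length(x$tissue_ids), sum(x$valid_mask),
              100 * mean(x$valid_mask)))
  invisible(x)
}

#' Convert FPKM to TPM
#'
#' Renormalizes each tissue column so that the non-missing entries sum to one
#' million: `TPM = FPKM / sum(FPKM) * 1e6`.  Missing entries (`NA`) are
#' excluded from the column sum and stay missing.
#'
#' @param fpkm genes x tissues non-negative numeric matrix, `NA` = missing.
#' @return Matrix of the same shape in TPM units.
#' @export
fpkm_to_tpm <- function(fpkm) {
  fpkm <- as.matrix(fpkm)
  if (any(fpkm < 0, na.rm = TRUE)) stop("FPKM values must be non-negative")
  csum <- colSums(fpkm, na.rm = TRUE)
  bad <- csum <= 0
  if (any(bad)) {
    nm <- colnames(fpkm)[bad]
    if (is.null(nm)) nm <- which(bad)
    stop("degenerate FPKM column (all zero or all missing) for tissue(s): ",
         paste(nm, collapse = ", "))
  }
  sweep(fpkm, 2, csum, "/") * 1e6
}

#' Apply detection thresholds to matched abundance matrices
#'
#' Entries below the detection threshold become missing (`NA`); comparisons
#' are inclusive, i.e. a value exactly at the threshold is kept.  Default
#' thresholds are 1 TPM and an iBAQ intensity of 5000.
#'
#' @param tpm,ibaq aligned genes x tissues matrices on the linear scale.
#' @param tpm_min,ibaq_min detection thresholds.
#' @return List with `tpm`, `ibaq` (thresholded, `NA` below threshold) and
#'   `valid_mask` (TRUE where both pass).
#' @export
apply_detection_thresholds <- function(tpm, ibaq, tpm_min = 1, ibaq_min = 5000) {
  if (!all(dim(tpm) == dim(ibaq)))
    stop("tpm and ibaq matrices are not aligned (dimension mismatch)")
  tpm[!is.na(tpm) & tpm < tpm_min] <- NA
  ibaq[!is.na(ibaq) & ibaq < ibaq_min] <- NA
  list(tpm = tpm, ibaq = ibaq, valid_mask = !is.na(tpm) & !is.na(ibaq))
}

#' Elementwise log2 with missing-value propagation
#'
#' @param m numeric matrix with non-missing entries strictly positive.
#' @return log2-transformed matrix; `NA` entries stay `NA`.
#' @export
log2_transform <- function(m) {
  if (any(m <= 0, na.rm = TRUE))
    stop("log2_transform: non-missing entries must be strictly positive")
  log2(m)
}

#' Build a ptr_dataset from linear-scale matrices
#'
#' Convenience wrapper: thresholds then log2-transforms matched TPM/iBAQ
#' matrices.
#'
#' @inheritParams apply_detection_thresholds
#' @return A [ptr_dataset].
#' @export
preprocess_expression <- function(tpm, ibaq, tpm_min = 1, ibaq_min = 5000) {
  thr <- apply_detection_thresholds(tpm, ibaq, tpm_min, ibaq_min)
  ptr_dataset(log2_transform(thr$tpm), log2_transform(thr$ibaq),
              gene_ids = rownames(tpm), tissue_ids = colnames(tpm))
}

#' Partition genes by matched data-point coverage
#'
#' Genes with at least 21 valid (matched) data points form the training set;
#' genes with exactly 20 are reserved as an independent hold-out set; genes
#' with fewer are excluded.
#'
#' @param dataset a [ptr_dataset].
#' @param min_train minimum valid points for training genes (default 21).
#' @param holdout_points exact valid-point count routed to the hold-out set
#'   (default 20).
#' @return List of class `coverage_partition` with `training_genes`,
#'   `holdout_genes`, `excluded_genes` and the per-gene `n_valid` counts.
#' @export
partition_by_coverage <- function(dataset, min_train = 21, holdout_points = 20) {
  n_valid <- rowSums(dataset$valid_mask)
  structure(list(
    training_genes = dataset$gene_ids[n_valid >= min_train],
    holdout_genes  = dataset$gene_ids[n_valid == holdout_points],
    excluded_genes = dataset$gene_ids[n_valid < holdout_points],
    n_valid        = stats::setNames(n_valid, dataset$gene_ids)
  ), class = "coverage_partition")
}

# ---- TSV I/O ---------------------------------------------------------------

#' Read an expression table
#'
#' Tab-separated, UTF-8, '.' decimal separator; header row of tissue IDs,
#' first column of gene IDs; empty cells are missing values.
#'
#' @param path file path.
#' @return Numeric matrix with gene-ID rownames and tissue-ID colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          na.strings = c("", "NA", "NaN"))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_tsv()]: missing values are written as empty
#' cells.
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @param id_col name of the gene-ID column (default "gene_id").
#' @export
write_expression_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

#' Write a processed dataset to a directory
#'
#' Emits `log2_tpm.tsv`, `log2_ibaq.tsv` and `valid_mask.tsv`.
#'
#' @param dataset a [ptr_dataset].
#' @param dir output directory (created if absent).
#' @export
write_ptr_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(dataset$log2_tpm, file.path(dir, "log2_tpm.tsv"))
  write_expression_tsv(dataset$log2_ibaq, file.path(dir, "log2_ibaq.tsv"))
  mask <- dataset$valid_mask * 1L
  write_expression_tsv(mask, file.path(dir, "valid_mask.tsv"))
  invisible(dir)
}

#' Read a processed dataset written by [write_ptr_dataset()]
#'
#' @param dir directory containing the three TSVs.
#' @return A [ptr_dataset].
#' @export
read_ptr_dataset <- function(dir) {
  ptr_dataset(read_expression_tsv(file.path(dir, "log2_tpm.tsv")),
              read_expression_tsv(file.path(dir, "log2_ibaq.tsv")))
}
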