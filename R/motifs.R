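# From trained weights to interpretable outputs: averaged weight heatmaps
# for the gradient parameter a, and sequence motifs recovered from the
# convolutional filters by a standardize -> position-mask -> offset-enumerate
# -> OPTICS -> dedup -> normalize pipeline.

#' Effective gradient-parameter weights of fitted models, averaged
#'
#' For every dense branch, computes the effective linear weight from each
#' input element to the output `a` (the Jacobian row of `a` evaluated at an
#' all-zero reference input, which for affine heads is exact) and averages
#' it over the supplied models (e.g. all repeats x folds of a CV run).
#'
#' @param models list of fitted [ptr_model] objects sharing one architecture.
#' @param features the `ptr_features` object the models were trained with.
#' @return Named list (one entry per dense feature) of weight vectors in
#'   input-element order.
#' @export
extract_gradient_weights <- function(models, features) {
  if (length(models) == 0) stop("empty model list")
  arch <- vapply(models[[1]]$branches, function(b) b$feature, "")
  for (m in models)
    if (!identical(vapply(m$branches, function(b) b$feature, ""), arch))
      stop("models have heterogeneous architectures")
  acc <- NULL
  for (m in models) {
    w <- gradient_weights_one(m, features)
    if (is.null(acc)) acc <- w
    else acc <- Map(`+`, acc, w)
  }
  lapply(acc, function(v) v / length(models))
}

# Jacobian row for output a at zero input, chained through branch dense
# layers and ReLU combine layers (ReLU derivative taken at bias point).
gradient_weights_one <- function(model, features) {
  # head Jacobian with respect to the concatenated latent vector
  latent_dims <- if (model$combined)
    vapply(model$params, function(p) length(p$b), 0)
  else
    vapply(model$branches, branch_output_dim, 0, features = features)
  J <- model$head$final$W[1, , drop = FALSE]  # row for output a
  if (length(model$head$hidden) > 0) {
    # forward an all-zero latent to get the ReLU gates at each layer
    acts <- list()
    v <- rep(0, sum(latent_dims))
    for (h in model$head$hidden) {
      pre <- as.vector(h$W %*% v + h$b)
      acts[[length(acts) + 1]] <- pre > 0
      v <- pmax(pre, 0)
    }
    for (i in rev(seq_along(model$head$hidden))) {
      h <- model$head$hidden[[i]]
      J <- J %*% (h$W * acts[[i]])
    }
  }
  out <- list()
  off <- 0
  for (j in seq_along(model$branches)) {
    br <- model$branches[[j]]
    q <- latent_dims[j]
    Jj <- J[, (off + 1):(off + q), drop = FALSE]
    off <- off + q
    if (br$type != "dense") next
    # weights are reported on the model's standardized input scale (the
    # scale on which they were learned); dividing by the per-dimension sd
    # would inflate near-constant inputs
    w <- if (model$combined) as.vector(Jj %*% model$params[[j]]$W)
         else as.vector(Jj)
    names(w) <- colnames(features$counts[[br$feature]])
    out[[br$feature]] <- w
  }
  out
}

#' Collect convolutional filters from fitted models into a filter bank
#'
#' @param models list of fitted [ptr_model] objects.
#' @param feature sequence feature name (`utr5`, `cds`, `utr3`, `pep`).
#' @return Object of class `filter_bank`: list of alphabet x width matrices
#'   with source IDs `model<i>.f<j>`.
#' @export
collect_filters <- function(models, feature) {
  filters <- list()
  for (i in seq_along(models)) {
    m <- models[[i]]
    for (j in seq_along(m$branches)) {
      br <- m$branches[[j]]
      if (br$type != "conv" || br$feature != feature) next
      Fm <- m$params[[j]]$F
      A <- if (feature == "pep") length(AA_ALPHABET) else length(NT_ALPHABET)
      alpha <- if (feature == "pep") AA_ALPHABET else NT_ALPHABET
      for (f in seq_len(ncol(Fm))) {
        mat <- matrix(Fm[, f], nrow = A, dimnames = list(alpha, NULL))
        filters[[paste0("model", i, ".f", f)]] <- mat
      }
    }
  }
  if (length(filters) == 0) stop("no convolutional filters for feature ", feature)
  structure(list(feature = feature, filters = filters), class = "filter_bank")
}

#' Standardize each filter to zero mean and unit standard deviation
#'
#' Filters are rescaled independently over all their entries; zero-variance
#' filters are dropped with a warning.
#'
#' @param bank a `filter_bank`.
#' @return The standardized `filter_bank`.
#' @export
standardize_filters <- function(bank) {
  if (length(bank$filters) == 0) stop("empty filter bank")
  out <- list()
  dropped <- 0
  for (nm in names(bank$filters)) {
    f <- bank$filters[[nm]]
    s <- stats::sd(as.vector(f))
    if (!is.finite(s) || s == 0) { dropped <- dropped + 1; next }
    out[[nm]] <- (f - mean(f)) / s
  }
  if (dropped > 0) warning(dropped, " constant filter(s) dropped")
  bank$filters <- out
  bank
}

#' Mask uninformative filter positions
#'
#' Keeps the contiguous span from the first to the last column whose
#' per-position standard deviation (across alphabet entries) exceeds
#' `std_cutoff`; internal low-variation columns are retained to preserve
#' spacing.  Returns `NULL` when no column passes.
#'
#' @param filter standardized alphabet x width matrix.
#' @param std_cutoff positional sd cutoff (default 0.2, strict >).
#' @return List with `filter` (trimmed matrix) and `kept` (original column
#'   index range), or `NULL`.
#' @export
mask_informative_positions <- function(filter, std_cutoff = 0.2) {
  sds <- apply(filter, 2, stats::sd)
  keep <- which(sds > std_cutoff)
  if (length(keep) == 0) return(NULL)
  span <- keep[1]:keep[length(keep)]
  list(filter = filter[, span, drop = FALSE], kept = range(keep))
}

#' Enumerate all offsets of a trimmed filter on a wider canvas
#'
#' @param filter alphabet x k matrix.
#' @param canvas_width canvas width W >= k.
#' @return List of W - k + 1 alphabet x W matrices; each carries its
#'   `offset` (0-based) as an attribute.
#' @export
enumerate_offsets <- function(filter, canvas_width) {
  k <- ncol(filter)
  if (canvas_width < k) stop("canvas narrower than filter")
  lapply(0:(canvas_width - k), function(off) {
    m <- matrix(0, nrow(filter), canvas_width)
    if (!is.null(rownames(filter))) rownames(m) <- rownames(filter)
    m[, (off + 1):(off + k)] <- filter
    attr(m, "offset") <- off
    m
  })
}

#' Cluster offset-enumerated filters with OPTICS
#'
#' Flattens the padded matrices and clusters them with OPTICS (Euclidean
#' metric) using xi extraction; xi defaults to 1e-2 for nucleotide and 5e-3
#' for amino-acid alphabets.
#'
#' @param padded list of equal-size padded matrices (each with `source` and
#'   `offset` attributes; see [prepare_filter_matrices()]).
#' @param alphabet_kind `"nucleotide"` or `"amino_acid"`.
#' @param xi override the per-alphabet default.
#' @param min_samples OPTICS neighbourhood size (default 5).
#' @return Integer cluster labels (-1 = noise), one per matrix.
#' @export
cluster_filters <- function(padded, alphabet_kind = c("nucleotide", "amino_acid"),
                            xi = NULL, min_samples = 5) {
  alphabet_kind <- match.arg(alphabet_kind)
  if (is.null(xi)) xi <- if (alphabet_kind == "nucleotide") 1e-2 else 5e-3
  X <- t(vapply(padded, as.vector, numeric(length(padded[[1]]))))
  if (nrow(X) < min_samples) {
    warning("too few matrices to cluster; all points labelled noise")
    return(rep(-1L, nrow(X)))
  }
  optics_xi(X, min_samples = min_samples, xi = xi)$labels
}

#' Standardize, trim and offset-enumerate a filter bank
#'
#' Canvas width defaults to the maximum trimmed width in the bank plus
#' (filter width - 1) positions of slack.
#'
#' @param bank a `filter_bank` (raw; standardization is applied here).
#' @param std_cutoff positional sd cutoff.
#' @param canvas_width optional canvas override.
#' @return List of padded matrices, each with `source` (filter ID) and
#'   `offset` attributes.
#' @export
prepare_filter_matrices <- function(bank, std_cutoff = 0.2, canvas_width = NULL) {
  raw_width <- ncol(bank$filters[[1]])
  bank <- standardize_filters(bank)
  trimmed <- list()
  for (nm in names(bank$filters)) {
    tr <- mask_informative_positions(bank$filters[[nm]], std_cutoff)
    if (!is.null(tr)) trimmed[[nm]] <- tr$filter
  }
  if (length(trimmed) == 0) stop("no filter has informative positions")
  if (is.null(canvas_width))
    canvas_width <- max(vapply(trimmed, ncol, 0L)) + raw_width - 1
  padded <- list()
  for (nm in names(trimmed)) {
    for (m in enumerate_offsets(trimmed[[nm]], canvas_width)) {
      attr(m, "source") <- nm
      padded[[length(padded) + 1]] <- m
    }
  }
  padded
}

#' Order clusters by size and de-duplicate source filters
#'
#' Clusters are ranked by member count (descending); walking down the
#' ranking, each source filter ID is kept only in the first cluster where it
#' appears (its copies at other offsets or in smaller clusters are removed);
#' cluster sizes are recomputed after de-duplication.
#'
#' @param labels integer labels from [cluster_filters()].
#' @param padded the matrix list the labels refer to.
#' @return List of clusters, each a list with `members` (matrices) and
#'   `sources`; ordered by post-dedup size, empty clusters removed.
#' @export
dedup_and_rank <- function(labels, padded) {
  ids <- sort(unique(labels[labels >= 0]))
  if (length(ids) == 0) return(list())
  sizes <- vapply(ids, function(k) sum(labels == k), 0L)
  ids <- ids[order(-sizes)]
  seen <- character(0)
  out <- list()
  for (k in ids) {
    idx <- which(labels == k)
    src <- vapply(padded[idx], function(m) attr(m, "source"), "")
    keep_first <- !duplicated(src) & !(src %in% seen)
    idx <- idx[keep_first]
    src <- src[keep_first]
    seen <- c(seen, src)
    if (length(idx) == 0) next
    out[[length(out) + 1]] <- list(members = padded[idx], sources = src,
                                   label = k)
  }
  ord <- order(-vapply(out, function(cl) length(cl$sources), 0L))
  out[ord]
}

#' Average, scale and trim a cluster into a motif
#'
#' Members are averaged on the shared canvas, scaled so the largest peak is
#' exactly 1, recentred on that peak, and entries <= 0.1 are zeroed.
#'
#' @param cluster element of [dedup_and_rank()] output.
#' @param source_feature feature label carried into the result.
#' @param rank rank carried into the result.
#' @return Object of class `motif_cluster` with `consensus`, `n_members`,
#'   `source_feature`, `rank`; or `NULL` when the averaged matrix has no
#'   positive entries.
#' @export
normalize_cluster <- function(cluster, source_feature = "", rank = NA_integer_) {
  stopifnot(length(cluster$members) >= 1)
  avg <- Reduce(`+`, cluster$members) / length(cluster$members)
  mx <- max(avg)
  if (mx <= 0) {
    warning("cluster consensus has non-positive maximum; skipped")
    return(NULL)
  }
  avg <- avg / mx
  # recentre the canvas on the peak column
  peak <- which(avg == 1, arr.ind = TRUE)[1, 2]
  W <- ncol(avg)
  centre <- (W + 1) %/% 2
  shift <- centre - peak
  rec <- matrix(0, nrow(avg), W, dimnames = dimnames(avg))
  src_cols <- seq_len(W) - shift
  ok <- src_cols >= 1 & src_cols <= W
  rec[, which(ok)] <- avg[, src_cols[ok]]
  rec[rec <= 0.1] <- 0
  structure(list(consensus = rec, n_members = length(cluster$sources),
                 source_feature = source_feature, rank = rank),
            class = "motif_cluster")
}

#' Full motif-discovery pipeline from fitted models
#'
#' @param models list of fitted [ptr_model] objects (e.g. `cv$models`).
#' @param feature sequence feature to analyse.
#' @param std_cutoff,canvas_width,xi,min_samples pipeline knobs.
#' @return List of `motif_cluster` objects, ranked by member count.
#' @export
discover_motifs <- function(models, feature, std_cutoff = 0.2,
                            canvas_width = NULL, xi = NULL, min_samples = 5) {
  bank <- collect_filters(models, feature)
  padded <- prepare_filter_matrices(bank, std_cutoff, canvas_width)
  kind <- if (feature == "pep") "amino_acid" else "nucleotide"
  labels <- cluster_filters(padded, kind, xi = xi, min_samples = min_samples)
  ranked <- dedup_and_rank(labels, padded)
  out <- list()
  for (i in seq_along(ranked)) {
    mc <- normalize_cluster(ranked[[i]], source_feature = feature, rank = i)
    if (!is.null(mc)) out[[length(out) + 1]] <- mc
  }
  out
}

#' Best positional match between a motif cluster and a k-mer
#'
#' Slides the k-mer along the consensus canvas and counts positions where
#' the consensus argmax letter equals the k-mer letter (only columns with a
#' positive consensus value count as informative).
#'
#' @param motif a `motif_cluster`.
#' @param kmer character string over the motif's alphabet.
#' @return Maximum number of matching positions over all alignments.
#' @export
motif_match_positions <- function(motif, kmer) {
  cons <- motif$consensus
  letters_k <- strsplit(kmer, "")[[1]]
  k <- length(letters_k)
  W <- ncol(cons)
  if (W < k) return(0L)
  alpha <- rownames(cons)
  arg <- apply(cons, 2, function(col)
    if (max(col) > 0) alpha[which.max(col)] else NA_character_)
  best <- 0L
  for (off in 0:(W - k)) {
    m <- sum(arg[(off + 1):(off + k)] == letters_k, na.rm = TRUE)
    best <- max(best, m)
  }
  best
}

#' Write motifs in MEME minimal format
#'
#' Consensus matrices are written as letter value matrices on the cluster's
#' normalized 0..1 scale (these are scaled model weights, not probabilities;
#' columns are additionally renormalized to sum to 1 so standard logo tools
#' accept the file).
#'
#' @param motifs list of `motif_cluster` objects.
#' @param path output file.
#' @param rna render T as U in nucleotide motif names (display only).
#' @export
write_meme <- function(motifs, path, rna = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(motifs) == 0) { writeLines("MEME version 4", con); return(invisible(path)) }
  alpha <- rownames(motifs[[1]]$consensus)
  writeLines(c("MEME version 4", "",
               paste0("ALPHABET= ", paste(alpha, collapse = "")), "",
               "strands: +", ""), con)
  for (m in motifs) {
    cons <- m$consensus
    keep <- which(colSums(cons) > 0)
    if (length(keep) == 0) next
    cons <- cons[, min(keep):max(keep), drop = FALSE]
    probs <- apply(cons, 2, function(col) {
      s <- sum(col); if (s > 0) col / s else rep(1 / length(col), length(col))
    })
    nm <- sprintf("%s_cluster%d_n%d", m$source_feature, m$rank, m$n_members)
    if (rna) nm <- gsub("T", "U", nm)
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= %d w= %d nsites= %d E= 0",
      nrow(probs), ncol(probs), m$n_members), con)
    for (j in seq_len(ncol(probs)))
      writeLines(paste(sprintf("%.6f", probs[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}
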