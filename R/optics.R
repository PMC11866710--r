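# OPTICS (Ordering Points To Identify the Clustering Structure) with
# xi-based cluster extraction.  Quadratic-time implementation suitable for
# the few thousand filter vectors produced by the motif pipeline; behaviour
# mirrors the widely used scikit-learn implementation (core distance to the
# min_samples-th neighbour counting the point itself, reachability ordering
# by repeated minimum, steep-area xi extraction with predecessor correction)
# so published xi values transfer directly.

#' OPTICS clustering with xi extraction
#'
#' @param x numeric matrix, one observation per row.
#' @param min_samples neighbourhood size defining core distances and the
#'   maximum run of non-steep points inside a steep area (default 5).
#' @param xi steepness parameter for cluster extraction.
#' @param min_cluster_size minimum cluster size (default `min_samples`).
#' @return List with `labels` (0-based cluster ids, -1 = noise), `ordering`
#'   (1-based visit order), `reachability`, `predecessor` and `clusters`
#'   (matrix of start/end positions in the ordering, 1-based).
#' @export
optics_xi <- function(x, min_samples = 5, xi = 0.05,
                      min_cluster_size = min_samples) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < min_samples) {
    warning("fewer points than min_samples; returning all-noise result")
    return(list(labels = rep(-1L, n), ordering = seq_len(n),
                reachability = rep(Inf, n), predecessor = rep(NA_integer_, n),
                clusters = matrix(integer(0), ncol = 2)))
  }
  d <- as.matrix(stats::dist(x))
  # core distance: distance to the min_samples-th nearest point, self counted
  core <- apply(d, 1, function(r) sort(r)[min_samples])
  reach <- rep(Inf, n)
  pred <- rep(NA_integer_, n)
  processed <- rep(FALSE, n)
  ordering <- integer(n)
  for (i in seq_len(n)) {
    cand <- which(!processed)
    p <- cand[which.min(reach[cand])]
    processed[p] <- TRUE
    ordering[i] <- p
    unproc <- which(!processed)
    if (length(unproc) > 0) {
      newr <- pmax(core[p], d[p, unproc])
      upd <- newr < reach[unproc]
      reach[unproc[upd]] <- newr[upd]
      pred[unproc[upd]] <- p
    }
  }
  clusters <- xi_extract_clusters(reach[ordering], pred[ordering], ordering,
                                  xi, min_samples, min_cluster_size)
  labels <- rep(-1L, n)
  lab <- 0L
  if (nrow(clusters) > 0) {
    lab_ord <- rep(-1L, n)
    for (k in seq_len(nrow(clusters))) {
      rng <- clusters[k, 1]:clusters[k, 2]
      if (all(lab_ord[rng] == -1L)) {
        lab_ord[rng] <- lab
        lab <- lab + 1L
      }
    }
    labels[ordering] <- lab_ord
  }
  list(labels = labels, ordering = ordering, reachability = reach,
       predecessor = pred, clusters = clusters)
}

# Extend a steep region: continue while points stay steep, tolerating at
# most min_samples consecutive merely-(up/down)ward points.
xi_extend_region <- function(steep, xward, start, min_samples) {
  non_xward <- 0
  index <- start
  end <- start
  n <- length(steep)
  while (index <= n) {
    if (steep[index]) {
      non_xward <- 0
      end <- index
    } else if (!xward[index]) {
      non_xward <- non_xward + 1
      if (non_xward > min_samples) break
    } else {
      return(end)
    }
    index <- index + 1
  }
  end
}

xi_update_sdas <- function(sdas, mib, xi_complement, rplot) {
  if (is.infinite(mib)) return(list())
  keep <- Filter(function(s) mib <= rplot[s$start] * xi_complement, sdas)
  lapply(keep, function(s) { s$mib <- max(s$mib, mib); s })
}

# Shrink the cluster right edge until its last point's predecessor lies
# inside the cluster (avoids annexing points reachable only through points
# outside the cluster).
xi_correct_predecessor <- function(rplot, pplot, ordering, s, e) {
  while (s < e) {
    if (rplot[s] > rplot[e]) return(c(s, e))
    p_e <- pplot[e]
    if (!is.na(p_e) && p_e %in% ordering[s:(e - 1)]) return(c(s, e))
    e <- e - 1
  }
  c(NA_integer_, NA_integer_)
}

xi_extract_clusters <- function(rplot, pplot, ordering, xi, min_samples,
                                min_cluster_size) {
  n <- length(rplot)
  rp <- c(rplot, Inf)
  xic <- 1 - xi
  ratio <- rp[seq_len(n)] / rp[seq_len(n) + 1]
  steep_up <- !is.na(ratio) & ratio <= xic
  steep_down <- !is.na(ratio) & ratio >= 1 / xic
  # Inf/Inf gives NaN: treat a drop from Inf as steep down, never steep up
  infpair <- is.na(ratio)
  steep_down[infpair] <- FALSE
  up <- !is.na(ratio) & ratio < 1
  down <- !is.na(ratio) & ratio > 1
  sdas <- list()
  clusters <- list()
  index <- 1
  mib <- 0
  for (steep_index in which(steep_up | steep_down)) {
    if (steep_index < index) next
    mib <- max(mib, max(rp[index:steep_index]))
    if (steep_down[steep_index]) {
      sdas <- xi_update_sdas(sdas, mib, xic, rp)
      d_start <- steep_index
      d_end <- xi_extend_region(steep_down, up, d_start, min_samples)
      sdas[[length(sdas) + 1]] <- list(start = d_start, end = d_end, mib = 0)
      index <- d_end + 1
      mib <- rp[index]
    } else {
      sdas <- xi_update_sdas(sdas, mib, xic, rp)
      u_start <- steep_index
      u_end <- xi_extend_region(steep_up, down, u_start, min_samples)
      index <- u_end + 1
      mib <- rp[index]
      u_clusters <- list()
      for (dd in sdas) {
        c_start <- dd$start
        c_end <- u_end
        if (rp[c_end + 1] * xic < dd$mib) next
        d_max <- rp[dd$start]
        if (d_max * xic >= rp[c_end + 1]) {
          while (c_start < dd$end && rp[c_start + 1] > rp[c_end + 1])
            c_start <- c_start + 1
        } else if (rp[c_end + 1] * xic >= d_max) {
          while (c_end > u_start && rp[c_end - 1] > d_max)
            c_end <- c_end - 1
        }
        ce <- xi_correct_predecessor(rp, pplot, ordering, c_start, c_end)
        c_start <- ce[1]; c_end <- ce[2]
        if (is.na(c_start)) next
        if (c_end - c_start + 1 < min_cluster_size) next
        if (c_start > dd$end) next
        if (c_end < u_start) next
        u_clusters[[length(u_clusters) + 1]] <- c(c_start, c_end)
      }
      clusters <- c(clusters, rev(u_clusters))
    }
  }
  if (length(clusters) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, clusters)
}
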