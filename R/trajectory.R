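#' Z-score expression trajectories
#'
#' Standardizes each gene's trajectory so that clustering compares shapes,
#' not expression levels: for gene g, the replicate mean of normalized
#' expression at each sampling point has the gene's overall mean (across all
#' samples) subtracted and is divided by the gene's overall standard
#' deviation across all samples. The replicate-count-weighted mean of each
#' row is therefore exactly zero, including under unbalanced designs.
#' Zero-variance genes cannot be standardized and are dropped with a
#' warning.
#'
#' @param norm_counts Normalized expression matrix genes x samples (e.g.
#'   from [normalize_counts()], optionally `log1p`-transformed).
#' @param samples Sample table; `sampling_point` groups the columns.
#' @param genes Genes to include (default: all rows).
#' @return Matrix genes x sampling points of class `trajectory_matrix`,
#'   with per-point replicate counts in `attr(, "replicates")` and any
#'   dropped genes in `attr(, "excluded")`.
#' @export
zscore_trajectories <- function(norm_counts, samples,
                                genes = rownames(norm_counts)) {
  norm_counts <- as.matrix(norm_counts)
  if (!all(genes %in% rownames(norm_counts))) {
    stop("input error: some requested genes are absent from the matrix")
  }
  m <- norm_counts[genes, samples$sample_id, drop = FALSE]
  sp <- droplevels(factor(samples$sampling_point))
  n_t <- as.vector(table(sp))
  if (any(n_t < 1L)) stop("input error: every sampling point needs >= 1 sample")

  ind <- stats::model.matrix(~ 0 + sp)
  point_means <- (m %*% ind) %*% diag(1 / n_t, length(n_t))
  colnames(point_means) <- levels(sp)
  overall_mean <- rowMeans(m)
  overall_sd <- apply(m, 1, stats::sd)

  keep <- overall_sd > 1e-12
  if (!all(keep)) {
    warning(sum(!keep), " constant-expression gene(s) excluded: ",
            paste(utils::head(genes[!keep], 5), collapse = ", "),
            if (sum(!keep) > 5) ", ..." else "")
  }
  z <- (point_means[keep, , drop = FALSE] - overall_mean[keep]) /
    overall_sd[keep]
  structure(z, class = c("trajectory_matrix", "matrix", "array"),
            replicates = stats::setNames(n_t, levels(sp)),
            excluded = genes[!keep])
}

#' Pearson dissimilarity between trajectories
#'
#' `d(g, h) = 1 - r(z_g, z_h)` on the Z-score rows, giving distances in
#' `[0, 2]`: 0 for identical shapes, 2 for perfectly anticorrelated ones.
#'
#' @param traj Trajectory matrix (genes x sampling points), >= 3 points.
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
pearson_dissimilarity <- function(traj) {
  z <- unclass(traj)
  if (ncol(z) < 3L) stop("input error: need at least 3 sampling points")
  row_sd <- apply(z, 1, stats::sd)
  if (any(row_sd <= 1e-12)) {
    stop("input error: correlation undefined for constant trajectory of gene(s): ",
         paste(utils::head(rownames(z)[row_sd <= 1e-12], 5), collapse = ", "))
  }
  d <- 1 - stats::cor(t(z))
  d[d < 0] <- 0
  d[d > 2] <- 2
  diag(d) <- 0
  d
}

linkage_method <- function(linkage) {
  switch(match.arg(linkage, c("complete", "average", "ward")),
         complete = "complete", average = "average", ward = "ward.D2")
}

#' Hierarchical clustering of trajectory dissimilarities
#'
#' Agglomerative clustering (via `stats::hclust`) under complete, average,
#' or Ward linkage ("ward" maps to `ward.D2`, Ward's criterion on the
#' dissimilarities themselves).
#'
#' @param dissim Symmetric dissimilarity matrix (or `dist`).
#' @param linkage One of `"complete"` (default), `"average"`, `"ward"`.
#' @return An `hclust` tree (merge sequence, heights, leaf order) with the
#'   requested linkage recorded in `attr(, "linkage")`.
#' @export
hierarchical_cluster <- function(dissim, linkage = "complete") {
  d <- if (inherits(dissim, "dist")) dissim else stats::as.dist(dissim)
  if (anyNA(d) || any(!is.finite(d))) {
    stop("input error: dissimilarity matrix contains NA/NaN/Inf")
  }
  hc <- stats::hclust(d, method = linkage_method(linkage))
  attr(hc, "linkage") <- linkage
  hc
}

#' Cut a dendrogram into k clusters
#'
#' Cuts the tree into exactly `k` groups and relabels the clusters `1..k`
#' by their position in the dendrogram leaf order, so cluster indices are a
#' stable, tree-ordered canonical labeling (independent of gene input
#' order).
#'
#' @param dendro An `hclust` tree.
#' @param k Number of clusters, `1 <= k <= n` leaves.
#' @return Object of class `cluster_assignment`: `cluster` (named integer
#'   vector gene -> cluster), `k`, `sizes`.
#' @export
cut_clusters <- function(dendro, k) {
  n <- length(dendro$order)
  if (k < 1 || k > n) stop("parameter error: k must be in [1, n]")
  ct <- stats::cutree(dendro, k = k)
  leaf_first <- unique(ct[dendro$order])
  cluster <- match(ct, leaf_first)
  names(cluster) <- names(ct)
  structure(
    list(cluster = cluster, k = as.integer(k),
         sizes = tabulate(cluster, nbins = k)),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment: ", length(x$cluster), " genes in ", x$k,
      " clusters (sizes ", paste(x$sizes, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Scan candidate cluster numbers against a size band
#'
#' For each candidate `k`, reports the resulting cluster-size distribution
#' and how many clusters fall outside a target size band (used to avoid
#' clusters too small to test for enrichment or too large to be
#' informative). Recommends the smallest `k` with zero violations if one
#' exists, else the `k` minimizing violations — but never chooses silently:
#' the caller passes `k` to [cut_clusters()] explicitly.
#'
#' @param dendro An `hclust` tree.
#' @param size_band Numeric `(lo, hi)`, `lo < hi`.
#' @param k_range Candidate values of `k`.
#' @return data.frame `k`, `min_size`, `max_size`, `n_outside_band`, with
#'   the recommendation in `attr(, "recommended_k")`.
#' @export
scan_k <- function(dendro, size_band, k_range) {
  if (length(k_range) == 0L) stop("parameter error: empty k range")
  if (size_band[1] >= size_band[2]) stop("parameter error: need lo < hi in size band")
  rows <- lapply(sort(unique(as.integer(k_range))), function(k) {
    sizes <- cut_clusters(dendro, k)$sizes
    data.frame(k = k, min_size = min(sizes), max_size = max(sizes),
               n_outside_band = sum(sizes < size_band[1] | sizes > size_band[2]))
  })
  out <- do.call(rbind, rows)
  ok <- out$k[out$n_outside_band == 0]
  rec <- if (length(ok)) min(ok) else out$k[which.min(out$n_outside_band)]
  attr(out, "recommended_k") <- rec
  out
}
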