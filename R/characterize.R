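#' Mean Z-score trajectory per cluster
#'
#' @param traj Trajectory matrix (genes x sampling points).
#' @param assignment `cluster_assignment` from [cut_clusters()].
#' @return Matrix clusters x sampling points: unweighted mean over member
#'   genes of the Z-score at each point.
#' @export
cluster_mean_curves <- function(traj, assignment) {
  z <- unclass(traj)
  cl <- assignment$cluster[rownames(z)]
  if (anyNA(cl)) stop("input error: genes in trajectory matrix missing from assignment")
  if (any(tabulate(cl, nbins = assignment$k) == 0L)) {
    stop("input error: empty cluster")
  }
  sums <- rowsum(z, group = cl)
  m <- sums / as.vector(table(factor(cl, levels = seq_len(assignment$k))))
  rownames(m) <- seq_len(assignment$k)
  m
}

#' Smooth a cluster mean trajectory with a restricted cubic spline
#'
#' Least-squares natural (restricted) cubic spline of the per-point mean
#' Z-scores on day, with `n_knots` knots at day quantiles; linear beyond
#' the boundary knots. This curve is for reporting and plotting only — the
#' Linear/Complex classification never uses it.
#'
#' @param mean_z Mean Z-score per sampling point.
#' @param days Day of each sampling point.
#' @param n_knots Number of knots (default 5). With fewer distinct days
#'   than knots the fit falls back to a straight line with a warning.
#' @param grid_n Number of evaluation points across the day range.
#' @return data.frame with columns `day` and `value`.
#' @export
smooth_curve <- function(mean_z, days, n_knots = 5, grid_n = 101) {
  stopifnot(length(mean_z) == length(days))
  grid <- seq(min(days), max(days), length.out = grid_n)
  if (length(unique(days)) < n_knots) {
    warning("fewer distinct days than knots; falling back to a linear fit")
    fit <- stats::lm(mean_z ~ days)
    return(data.frame(day = grid,
                      value = unname(stats::predict(fit,
                        newdata = data.frame(days = grid)))))
  }
  probs <- seq(0, 1, length.out = n_knots)
  knots <- unname(stats::quantile(days, probs, type = 7))
  basis <- splines::ns(days, knots = knots[-c(1, n_knots)],
                       Boundary.knots = knots[c(1, n_knots)])
  fit <- stats::lm(mean_z ~ basis)
  gb <- splines::ns(grid, knots = knots[-c(1, n_knots)],
                    Boundary.knots = knots[c(1, n_knots)])
  data.frame(day = grid,
             value = drop(cbind(1, gb) %*% stats::coef(fit)))
}

#' Classify one cluster trajectory as LinearUp, LinearDown, or Complex
#'
#' Ordinary least squares of the per-sampling-point mean Z-scores (one
#' value per point, unweighted) on day, with a two-sided t-test on the
#' slope. The trajectory is "Linear" when the slope p-value is below the
#' Bonferroni-corrected family threshold `family_alpha / k` (0.05/28 =
#' 0.002 at the canonical 28 clusters), signed Up/Down by the slope;
#' otherwise "Complex". A numerically exact linear fit is classified by the
#' slope sign with `p = 0`.
#'
#' @param mean_z Mean Z-score per sampling point (>= 3 points).
#' @param days Day of each point (must vary).
#' @param family_alpha Family-wise alpha (default 0.05).
#' @param k Number of clusters in the family (Bonferroni denominator).
#' @return List: `slope`, `p_value`, `trajectory_class`, `threshold`.
#' @export
#' @examples
#' classify_cluster(seq(-1, 1, length.out = 15), default_sampling_days(), k = 28)
classify_cluster <- function(mean_z, days, family_alpha = 0.05, k) {
  if (length(mean_z) < 3L) stop("input error: need >= 3 sampling points")
  if (stats::var(days) <= 0) stop("input error: days must vary")
  stopifnot(k >= 1)
  fit <- stats::lm(mean_z ~ days)
  slope <- unname(stats::coef(fit)[2])
  rss <- sum(stats::residuals(fit)^2)
  if (rss < 1e-18) {
    p <- if (abs(slope) > 1e-12) 0 else 1
  } else {
    p <- summary(fit)$coefficients[2, 4]
  }
  threshold <- family_alpha / k
  cls <- if (!is.na(p) && p < threshold) {
    if (slope > 0) "LinearUp" else "LinearDown"
  } else {
    "Complex"
  }
  list(slope = slope, p_value = p, trajectory_class = cls,
       threshold = threshold)
}

#' Name clusters by class and dendrogram position
#'
#' Clusters (already in dendrogram leaf order, as produced by
#' [cut_clusters()]) are numbered consecutively within each trajectory
#' class, giving names like `"LinearUp-1"`, `"Complex-3"`.
#'
#' @param trajectory_class Character vector of classes, one per cluster, in
#'   dendrogram order.
#' @return Character vector of names, same order.
#' @export
name_clusters <- function(trajectory_class) {
  idx <- stats::ave(seq_along(trajectory_class), trajectory_class,
                    FUN = seq_along)
  paste0(trajectory_class, "-", idx)
}

#' Build full cluster profiles: mean curves, classification, names
#'
#' Convenience wrapper running [cluster_mean_curves()],
#' [classify_cluster()] and [name_clusters()] over all clusters of an
#' assignment.
#'
#' @param traj Trajectory matrix.
#' @param assignment `cluster_assignment`.
#' @param days Day of each sampling point (columns of `traj`).
#' @param family_alpha Family-wise alpha for the Bonferroni rule.
#' @return Object of class `cluster_profiles`: data.frame `profiles`
#'   (`cluster`, `name`, `trajectory_class`, `slope`, `p_value`,
#'   `threshold`, `n_genes`) plus the `mean_curves` matrix and `days`.
#' @export
characterize_clusters <- function(traj, assignment, days,
                                  family_alpha = 0.05) {
  mc <- cluster_mean_curves(traj, assignment)
  stopifnot(length(days) == ncol(mc))
  k <- assignment$k
  cls <- lapply(seq_len(k), function(i) {
    classify_cluster(mc[i, ], days, family_alpha = family_alpha, k = k)
  })
  profiles <- data.frame(
    cluster = seq_len(k),
    trajectory_class = vapply(cls, `[[`, character(1), "trajectory_class"),
    slope = vapply(cls, `[[`, numeric(1), "slope"),
    p_value = vapply(cls, `[[`, numeric(1), "p_value"),
    threshold = vapply(cls, `[[`, numeric(1), "threshold"),
    n_genes = assignment$sizes,
    stringsAsFactors = FALSE
  )
  profiles$name <- name_clusters(profiles$trajectory_class)
  profiles <- profiles[, c("cluster", "name", "trajectory_class", "slope",
                           "p_value", "threshold", "n_genes")]
  structure(list(profiles = profiles, mean_curves = mc, days = days,
                 family_alpha = family_alpha),
            class = "cluster_profiles")
}

#' @export
print.cluster_profiles <- function(x, ...) {
  cat("cluster_profiles:", nrow(x$profiles), "clusters (threshold ",
      format(round(x$profiles$threshold[1], 3), nsmall = 3), ")\n")
  print(x$profiles, row.names = FALSE)
  invisible(x)
}
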