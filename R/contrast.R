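#' Two-timepoint young-versus-old differential expression
#'
#' Reanalyzes the count matrix as a classical 2-group design: samples from
#' `young_days` versus samples from `old_days`, NB GLM with a single group
#' covariate, Wald test, BH adjustment. Direction of change with age is the
#' sign of the fitted old-versus-young log2 fold change (an exact zero is
#' called "up"; probability ~0).
#'
#' @param counts Integer matrix genes x samples.
#' @param samples Sample table covering the counts columns.
#' @param young_days,old_days Disjoint sets of sampling days.
#' @param alpha Adjusted-p threshold for the `significant` flag.
#' @param dispersion `NULL` (estimate under the group model), scalar, or
#'   per-gene vector as in [run_three_analyses()].
#' @return Object of class `contrast_result`: data.frame `table`
#'   (`gene_id`, `log2_fold_change`, `statistic`, `p_value`, `adjusted_p`,
#'   `direction`, `significant`) plus `young_days`, `old_days`, `alpha`.
#' @export
two_group_de <- function(counts, samples, young_days = c(3, 6),
                         old_days = 59, alpha = 0.05, dispersion = NULL) {
  if (length(intersect(young_days, old_days)) > 0) {
    stop("design error: young and old day sets overlap")
  }
  keep <- samples$day %in% c(young_days, old_days)
  sub <- samples[keep, , drop = FALSE]
  if (!any(sub$day %in% young_days) || !any(sub$day %in% old_days)) {
    stop("design error: both groups must be non-empty")
  }
  counts <- as.matrix(counts)[, sub$sample_id, drop = FALSE]
  expressed <- rowSums(counts) >= 1
  counts <- counts[expressed, , drop = FALSE]
  genes <- rownames(counts)
  n_g <- nrow(counts)

  sf <- size_factors_median_of_ratios(counts)
  off <- log(sf)
  old <- as.numeric(sub$day %in% old_days)
  X <- cbind(`(Intercept)` = 1, old = old)

  if (is.null(dispersion)) {
    disp <- estimate_dispersion(counts, sf, X)
  } else if (length(dispersion) == 1L) {
    disp <- rep(dispersion, n_g)
  } else if (!is.null(names(dispersion))) {
    disp <- unname(dispersion[genes])
    if (anyNA(disp)) stop("input error: dispersion vector missing some genes")
  } else {
    stop("input error: dispersion must be NULL, scalar, or named per-gene")
  }

  lfc <- numeric(n_g)
  stat <- numeric(n_g)
  pv <- numeric(n_g)
  for (g in seq_len(n_g)) {
    fit <- fit_nb_glm(counts[g, ], X, disp[g], offset = off)
    w <- wald_test(fit, "old")
    lfc[g] <- unname(fit$coefficients["old"]) / log(2)
    stat[g] <- w$statistic
    pv[g] <- w$p_value
  }
  adj <- bh_adjust(pv)
  tab <- data.frame(
    gene_id = genes, log2_fold_change = lfc, statistic = stat,
    p_value = pv, adjusted_p = adj,
    direction = ifelse(lfc >= 0, "up", "down"),
    significant = !is.na(adj) & adj < alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(table = tab, young_days = sort(young_days),
                 old_days = sort(old_days), alpha = alpha),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("contrast_result: young days {", paste(x$young_days, collapse = ","),
      "} vs old days {", paste(x$old_days, collapse = ","), "}: ",
      sum(x$table$significant), "/", nrow(x$table),
      " significant at adjusted p < ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Sliding old-window reanalysis
#'
#' Holds the young day set fixed and re-runs [two_group_de()] against every
#' sequential pair of older sampling days (e.g. days {10,14}, {14,17}, ...,
#' {55,59}), mimicking the spread of "old" timepoint choices across
#' published 2-timepoint studies.
#'
#' @inheritParams two_group_de
#' @return Named list of `contrast_result`s, one per window, in day order
#'   (names like `"d10_d14"`).
#' @export
sliding_old_window <- function(counts, samples, young_days = c(3, 6),
                               alpha = 0.05, dispersion = NULL) {
  days <- sort(unique(samples$day))
  if (length(days) < 4L) stop("design error: need >= 4 sampling days")
  old_candidates <- setdiff(days, young_days)
  if (length(old_candidates) < 2L) stop("design error: need >= 2 post-young days")
  windows <- lapply(seq_len(length(old_candidates) - 1L), function(i) {
    old_candidates[c(i, i + 1L)]
  })
  names(windows) <- vapply(windows, function(w) {
    sprintf("d%d_d%d", w[1], w[2])
  }, character(1))
  lapply(windows, function(w) {
    two_group_de(counts, samples, young_days = young_days, old_days = w,
                 alpha = alpha, dispersion = dispersion)
  })
}

#' Concordance between multitimepoint trajectories and a 2-timepoint contrast
#'
#' For each trajectory class (and each cluster), tallies how many of the
#' multitimepoint genes the 2-timepoint contrast recovers as significant,
#' how the recovered genes split between up- and down-calls, and — for the
#' Linear classes, whose expected direction is defined — the fraction of
#' recovered genes whose call matches the trajectory's sign.
#' `fraction_up + fraction_down + fraction_missed = 1` within each row.
#'
#' @param assignment `cluster_assignment` over the multitimepoint gene set.
#' @param profiles `cluster_profiles` giving each cluster's class.
#' @param contrast `contrast_result` from [two_group_de()].
#' @return data.frame of class `concordance_table` with rows per trajectory
#'   class (`level == "class"`) and per cluster (`level == "cluster"`):
#'   `name`, `n_genes`, `n_recovered`, `fraction_up`, `fraction_down`,
#'   `fraction_missed`, `direction_match` (NA for Complex / unrecovered).
#' @export
concordance <- function(assignment, profiles, contrast) {
  genes <- names(assignment$cluster)
  tab <- contrast$table
  if (length(intersect(genes, tab$gene_id)) == 0L) {
    stop("input error: gene universes of the two analyses do not overlap")
  }
  idx <- match(genes, tab$gene_id)
  sig <- !is.na(idx) & tab$significant[idx]
  dir <- ifelse(sig, tab$direction[idx], NA_character_)
  cl <- assignment$cluster
  pr <- profiles$profiles
  cls <- pr$trajectory_class[cl]
  expected <- c(LinearUp = "up", LinearDown = "down", Complex = NA)[cls]

  summarize <- function(sel, name, level) {
    n <- sum(sel)
    if (n == 0L) {
      return(data.frame(level = level, name = name, n_genes = 0L,
                        n_recovered = 0L, fraction_up = NA_real_,
                        fraction_down = NA_real_, fraction_missed = NA_real_,
                        direction_match = NA_real_,
                        stringsAsFactors = FALSE))
    }
    rec <- sig & sel
    up <- sum(rec & dir == "up", na.rm = TRUE)
    down <- sum(rec & dir == "down", na.rm = TRUE)
    obs_dir <- dir[rec]
    exp_dir <- expected[rec]
    match_frac <- if (sum(rec) > 0 && any(!is.na(exp_dir))) {
      mean(obs_dir == exp_dir, na.rm = TRUE)
    } else NA_real_
    data.frame(level = level, name = name, n_genes = n,
               n_recovered = sum(rec), fraction_up = up / n,
               fraction_down = down / n,
               fraction_missed = (n - sum(rec)) / n,
               direction_match = match_frac, stringsAsFactors = FALSE)
  }

  class_rows <- lapply(c("LinearUp", "LinearDown", "Complex"), function(cc) {
    sel <- cls == cc
    row <- summarize(sel, cc, "class")
    if (cc == "Complex") row$direction_match <- NA_real_
    row
  })
  cluster_rows <- lapply(seq_len(assignment$k), function(i) {
    row <- summarize(cl == i, pr$name[i], "cluster")
    if (pr$trajectory_class[i] == "Complex") row$direction_match <- NA_real_
    row
  })
  out <- do.call(rbind, c(class_rows, cluster_rows))
  rownames(out) <- NULL
  class(out) <- c("concordance_table", "data.frame")
  out
}
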