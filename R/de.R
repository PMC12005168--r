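#' Run the three aging differential-expression analyses
#'
#' The core multitimepoint design: each expressed gene (row sum >= 1 across
#' all samples) is tested three ways against the same negative-binomial GLM
#' engine —
#' \describe{
#'   \item{Day}{chronological age in days as a continuous covariate; Wald
#'     test on the slope.}
#'   \item{Survival}{physiological age, the fraction of the cohort dead at
#'     sampling, as a continuous covariate; Wald test on the slope.}
#'   \item{SamplingPoint}{the sampling points as a categorical factor;
#'     likelihood-ratio test of the full factor model against
#'     intercept-only, catching genes whose expression varies with age in
#'     ways neither continuous covariate captures.}
#' }
#' Dispersion is estimated once per gene under the full sampling-point
#' factor model (unless supplied) and shared by all fits, including both
#' sides of the LRT. Benjamini-Hochberg adjustment is applied within each
#' analysis; a gene is significant where `adjusted_p < alpha`. Genes whose
#' fit did not converge carry `NA` p-values and are never significant.
#'
#' @param counts Integer matrix genes x samples (column names matching
#'   `samples$sample_id`).
#' @param samples Sample table from [make_design()] or
#'   [read_sample_table()].
#' @param alpha Significance threshold on adjusted p-values.
#' @param dispersion `NULL` to estimate; otherwise a single value or a
#'   per-gene vector (named vectors are matched by gene).
#' @param shrink Passed to [estimate_dispersion()].
#' @return Object of class `de_result_set`: `tables` (one data.frame per
#'   analysis: `gene_id`, `statistic`, `p_value`, `adjusted_p`,
#'   `significant`), `membership` (`gene_id`, `in_day`, `in_survival`,
#'   `in_sampling_point`), `union_genes`, `background_genes`, `alpha`,
#'   `size_factors`, `dispersion`.
#' @export
run_three_analyses <- function(counts, samples, alpha = 0.05,
                               dispersion = NULL, shrink = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) ||
      !setequal(colnames(counts), samples$sample_id)) {
    stop("input error: count matrix columns must match samples$sample_id")
  }
  counts <- counts[, samples$sample_id, drop = FALSE]
  if (length(unique(samples$day)) < 3L) {
    stop("design error: at least 3 distinct sampling points are required")
  }

  expressed <- rowSums(counts) >= 1
  counts <- counts[expressed, , drop = FALSE]
  background <- rownames(counts)
  n_g <- nrow(counts)

  sf <- size_factors_median_of_ratios(counts)
  off <- log(sf)
  sp <- droplevels(factor(samples$sampling_point))
  X_sp <- stats::model.matrix(~sp)
  X_day <- cbind(`(Intercept)` = 1, day = samples$day)
  X_surv <- cbind(`(Intercept)` = 1, mortality = samples$mortality_fraction)
  X_0 <- matrix(1, nrow(samples), 1, dimnames = list(NULL, "(Intercept)"))

  if (is.null(dispersion)) {
    disp <- estimate_dispersion(counts, sf, X_sp, shrink = shrink)
  } else if (length(dispersion) == 1L) {
    disp <- rep(dispersion, n_g)
  } else if (!is.null(names(dispersion))) {
    disp <- unname(dispersion[background])
    if (anyNA(disp)) stop("input error: dispersion vector missing some genes")
  } else if (length(dispersion) == n_g) {
    disp <- dispersion
  } else {
    stop("input error: dispersion must be NULL, scalar, or per-gene")
  }

  stat <- matrix(NA_real_, n_g, 3,
                 dimnames = list(background, c("Day", "Survival", "SamplingPoint")))
  pval <- stat
  for (g in seq_len(n_g)) {
    y <- counts[g, ]
    a <- disp[g]
    wd <- wald_test(fit_nb_glm(y, X_day, a, offset = off), "day")
    ws <- wald_test(fit_nb_glm(y, X_surv, a, offset = off), "mortality")
    lr <- lrt_test(fit_nb_glm(y, X_sp, a, offset = off),
                   fit_nb_glm(y, X_0, a, offset = off))
    stat[g, ] <- c(wd$statistic, ws$statistic, lr$statistic)
    pval[g, ] <- c(wd$p_value, ws$p_value, lr$p_value)
  }

  tables <- lapply(colnames(stat), function(an) {
    adj <- bh_adjust(pval[, an])
    data.frame(gene_id = background, statistic = stat[, an],
               p_value = pval[, an], adjusted_p = adj,
               significant = !is.na(adj) & adj < alpha,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  names(tables) <- colnames(stat)

  membership <- data.frame(
    gene_id = background,
    in_day = tables$Day$significant,
    in_survival = tables$Survival$significant,
    in_sampling_point = tables$SamplingPoint$significant,
    stringsAsFactors = FALSE
  )
  union_genes <- membership$gene_id[membership$in_day | membership$in_survival |
                                      membership$in_sampling_point]

  structure(
    list(tables = tables, membership = membership, union_genes = union_genes,
         background_genes = background, alpha = alpha, size_factors = sf,
         dispersion = stats::setNames(disp, background)),
    class = "de_result_set"
  )
}

#' @export
print.de_result_set <- function(x, ...) {
  n_sig <- vapply(x$tables, function(t) sum(t$significant), integer(1))
  cat("de_result_set:", length(x$background_genes), "expressed genes,",
      "alpha =", x$alpha, "\n")
  cat("  significant:", paste(names(n_sig), n_sig, sep = " = ",
                              collapse = ", "), "\n")
  cat("  union:", length(x$union_genes), "genes\n")
  invisible(x)
}
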