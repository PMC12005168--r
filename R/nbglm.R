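#' Negative-binomial log-likelihood at fixed means
#'
#' @param y Integer counts.
#' @param mu Fitted means (same length).
#' @param dispersion NB dispersion alpha; `Var = mu + alpha * mu^2`. Values
#'   below `1e-12` are evaluated as Poisson.
#' @return Total log-likelihood.
#' @keywords internal
nb_loglik <- function(y, mu, dispersion) {
  if (dispersion < 1e-12) {
    sum(stats::dpois(y, lambda = mu, log = TRUE))
  } else {
    sum(stats::dnbinom(y, mu = mu, size = 1 / dispersion, log = TRUE))
  }
}

#' Fit a negative-binomial GLM with log link and known dispersion
#'
#' Iteratively reweighted least squares for one gene: log link, optional
#' offsets (log size factors), dispersion held fixed. Working weights are
#' `mu / (1 + alpha * mu)`, the inverse variance of the working response, so
#' the limit `alpha -> 0` recovers the Poisson GLM. Standard errors come
#' from the Fisher information `X' W X` at convergence. Convergence is
#' declared when the largest coefficient change drops below `tol`; fits that
#' do not converge within `maxit` iterations are returned flagged rather
#' than erroring, so callers can exclude them from inference.
#'
#' @param y Non-negative integer counts, one per sample.
#' @param design_matrix Numeric model matrix (full column rank).
#' @param dispersion NB dispersion alpha (>= 0).
#' @param offset Optional per-sample offset on the log scale (default 0).
#' @param tol Convergence tolerance on coefficients.
#' @param maxit Maximum IRLS iterations.
#' @return Object of class `nbfit`: `coefficients`, `standard_errors`,
#'   `log_likelihood`, `dispersion`, `converged`, `fitted`, `df` (number of
#'   coefficients).
#' @export
#' @examples
#' y <- rpois(10, 50)
#' f <- fit_nb_glm(y, matrix(1, 10, 1), dispersion = 0)
#' exp(f$coefficients)  # = mean(y)
fit_nb_glm <- function(y, design_matrix, dispersion, offset = NULL,
                       tol = 1e-8, maxit = 100L) {
  X <- as.matrix(design_matrix)
  n <- length(y)
  if (nrow(X) != n) stop("design error: nrow(design_matrix) != length(y)")
  if (qr(X)$rank < ncol(X)) stop("design error: design matrix is rank deficient")
  if (dispersion < 0) stop("parameter error: dispersion must be non-negative")
  if (is.null(offset)) offset <- rep(0, n)

  mu <- pmax(y, 0.5)
  eta <- log(mu)
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    w <- mu / (1 + dispersion * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    if (anyNA(beta_new)) break
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  w <- mu / (1 + dispersion * mu)
  info <- crossprod(X, X * w)
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, ncol(X)))
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("b", seq_len(ncol(X)))
  names(beta) <- names(se) <- cn
  structure(
    list(coefficients = beta, standard_errors = se,
         log_likelihood = nb_loglik(y, mu, dispersion),
         dispersion = dispersion, converged = converged,
         fitted = mu, df = ncol(X)),
    class = "nbfit"
  )
}

#' @export
print.nbfit <- function(x, ...) {
  cat("nbfit:", x$df, "coefficients, dispersion", signif(x$dispersion, 3),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(rbind(estimate = x$coefficients, se = x$standard_errors))
  invisible(x)
}

#' Wald test for one GLM coefficient
#'
#' Two-sided p-value from `z = beta / SE` against the standard normal.
#' Non-converged fits yield `NA` (excluded from significance downstream).
#'
#' @param fit An `nbfit`.
#' @param coef_index Index (or name) of the coefficient to test.
#' @return List with `statistic` (z) and `p_value`.
#' @export
wald_test <- function(fit, coef_index) {
  stopifnot(inherits(fit, "nbfit"))
  b <- fit$coefficients[coef_index]
  se <- fit$standard_errors[coef_index]
  if (!fit$converged || is.na(b) || is.na(se) || se <= 0) {
    return(list(statistic = NA_real_, p_value = NA_real_))
  }
  z <- unname(b / se)
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Likelihood-ratio test between nested NB fits
#'
#' Chi-squared test on `2 * (loglik_full - loglik_reduced)`; both fits must
#' use the same dispersion (estimated under the full model by the callers in
#' this package). A full-model likelihood materially below the reduced one
#' indicates a fitting failure and errors.
#'
#' @param fit_full,fit_reduced Nested `nbfit` objects.
#' @param df Degrees of freedom (difference in coefficient count); defaults
#'   to `fit_full$df - fit_reduced$df`.
#' @return List with `statistic` and `p_value` (`NA` if either fit failed).
#' @export
lrt_test <- function(fit_full, fit_reduced, df = fit_full$df - fit_reduced$df) {
  stopifnot(inherits(fit_full, "nbfit"), inherits(fit_reduced, "nbfit"), df >= 1)
  if (!fit_full$converged || !fit_reduced$converged) {
    return(list(statistic = NA_real_, p_value = NA_real_))
  }
  if (fit_full$log_likelihood < fit_reduced$log_likelihood - 1e-6) {
    stop("fitting error: full-model likelihood below reduced-model likelihood")
  }
  stat <- max(0, 2 * (fit_full$log_likelihood - fit_reduced$log_likelihood))
  list(statistic = stat, p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Direct implementation of the BH step-up procedure:
#' `adj_(i) = min_(j >= i) n * p_(j) / j`, capped at 1, on the sorted
#' p-values. `NA`s are excluded and reinserted; the effective `n` counts
#' only non-missing values.
#'
#' @param p_values Numeric vector in `[0, 1]`, `NA` allowed.
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("input error: p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(p_values))
  ok <- which(!is.na(p_values))
  n <- length(ok)
  if (n == 0L) return(out)
  ord <- order(p_values[ok])
  sorted <- p_values[ok][ord]
  adj <- pmin(1, rev(cummin(rev(sorted * n / seq_len(n)))))
  out[ok[ord]] <- adj
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: each sample's counts are divided by
#' the per-gene geometric mean across samples (using only genes positive in
#' every sample), and the median of those ratios is the sample's raw factor.
#' Factors are rescaled to geometric mean 1.
#'
#' @param counts Integer matrix genes x samples.
#' @return Positive numeric vector, one factor per sample (named if the
#'   matrix has column names).
#' @export
#' @examples
#' m <- rbind(c(10, 20), c(100, 200), c(4, 8))
#' size_factors_median_of_ratios(m)  # c(1/sqrt(2), sqrt(2))
size_factors_median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("normalization error: no gene has a nonzero count in every sample; ",
         "median-of-ratios needs at least one such gene (filter samples or ",
         "supply size factors directly)")
  }
  lc <- log(counts[pos, , drop = FALSE])
  loggeo <- rowMeans(lc)
  s <- exp(apply(lc - loggeo, 2, stats::median))
  s <- s / exp(mean(log(s)))
  stats::setNames(s, colnames(counts))
}

#' Divide counts by size factors
#' @param counts Matrix genes x samples.
#' @param size_factors Per-sample factors (defaults to median-of-ratios).
#' @return Numeric matrix of normalized counts.
#' @export
normalize_counts <- function(counts,
                             size_factors = size_factors_median_of_ratios(counts)) {
  sweep(as.matrix(counts), 2, size_factors, "/")
}

#' Estimate per-gene NB dispersion by profile maximum likelihood
#'
#' For each gene: fit the GLM at a method-of-moments starting dispersion,
#' then maximise the NB likelihood over dispersion with the fitted means
#' held fixed, refit, and profile once more. Estimates are floored at
#' `1e-8`; all-zero genes are reported at the floor and flagged. Optional
#' shrinkage moderates gene-wise estimates toward a fitted mean-dispersion
#' trend `alpha(mu) = a0 + a1 / mu` (off by default so simulations with
#' known dispersion can validate the gene-wise estimator directly).
#'
#' @param counts Integer matrix genes x samples.
#' @param size_factors Per-sample size factors.
#' @param design_matrix Model matrix used for the mean fit.
#' @param shrink Logical; moderate toward the trend (default `FALSE`).
#' @param floor Lower bound for estimates.
#' @return Numeric vector of dispersions (named by gene), with
#'   `attr(, "flagged")` marking all-zero genes.
#' @export
estimate_dispersion <- function(counts, size_factors, design_matrix,
                                shrink = FALSE, floor = 1e-8) {
  counts <- as.matrix(counts)
  X <- as.matrix(design_matrix)
  if (nrow(counts) == 0L) stop("input error: empty count matrix")
  if (ncol(counts) - ncol(X) < 2L) {
    stop("design error: need at least 2 residual degrees of freedom")
  }
  off <- log(size_factors)
  upper <- log(50)
  lower <- log(floor)
  n_g <- nrow(counts)
  est <- numeric(n_g)
  flagged <- logical(n_g)
  norm <- sweep(counts, 2, size_factors, "/")
  for (g in seq_len(n_g)) {
    y <- counts[g, ]
    if (all(y == 0L)) {
      est[g] <- floor
      flagged[g] <- TRUE
      next
    }
    m <- mean(norm[g, ])
    v <- stats::var(norm[g, ])
    a0 <- (v - m) / m^2
    if (!is.finite(a0) || a0 <= 0) a0 <- 0.01
    a <- a0
    for (cycle in 1:2) {
      fit <- fit_nb_glm(y, X, a, offset = off)
      opt <- stats::optimize(function(la) nb_loglik(y, fit$fitted, exp(la)),
                             interval = c(lower, upper), maximum = TRUE,
                             tol = 1e-6)
      a <- exp(opt$maximum)
    }
    est[g] <- max(a, floor)
  }
  if (shrink) {
    base_mean <- rowMeans(norm)
    use <- !flagged & est > 1e-4 & base_mean > 0
    if (sum(use) >= 10) {
      tr <- stats::lm(est[use] ~ I(1 / base_mean[use]))
      a0 <- max(stats::coef(tr)[1], floor)
      a1 <- max(stats::coef(tr)[2], 0)
      trend <- pmax(a0 + a1 / pmax(base_mean, 1e-8), floor)
      est[!flagged] <- exp((log(est[!flagged]) + log(trend[!flagged])) / 2)
    }
  }
  names(est) <- rownames(counts)
  attr(est, "flagged") <- flagged
  est
}
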