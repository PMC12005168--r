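#' Trajectory classes available in the synthetic generator
#' @return Character vector of class names.
#' @export
trajectory_classes <- function() {
  c("null", "linear_up", "linear_down", "midlife_peak", "wave")
}

# Round class proportions to integer counts that sum exactly to n:
# floor, then give the remainder to the classes with the largest
# fractional parts (ties broken by position).
round_class_counts <- function(n, proportions) {
  raw <- n * proportions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- raw - counts
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

# log2 trajectory template evaluated at u in [0,1] (scaled day).
# Amplitude conventions: linear templates span `effect` log2 units over the
# sampled lifespan; midlife_peak is a raised cosine with equal endpoints and
# peak `effect` above baseline; wave is one full sinusoid period of
# peak-to-trough amplitude `effect` (endpoints equal for any phase). The
# wave's phase is chosen so the template is orthogonal to the linear trend
# in day over the actual sampling grid — the wave class represents
# trend-free oscillation, so with uneven sampling days the phase that makes
# its least-squares day slope exactly zero is the defining one.
trajectory_template <- function(class, u, effect) {
  switch(class,
    null         = rep(0, length(u)),
    linear_up    = effect * u,
    linear_down  = -effect * u,
    midlife_peak = effect * (1 - cos(2 * pi * u)) / 2,
    wave         = {
      du <- u - mean(u)
      phi <- atan2(-sum(du * sin(2 * pi * u)), sum(du * cos(2 * pi * u)))
      (effect / 2) * sin(2 * pi * u + phi)
    },
    stop("unknown trajectory class: ", class)
  )
}

#' Generate per-gene trajectory truth for simulation
#'
#' Draws, for `n_genes` genes, a trajectory class, a baseline normalized
#' mean, a log2-scale effect size and a negative-binomial dispersion, and
#' builds each gene's expected normalized mean at every sampling day.
#' Templates are parameterised on the log2 scale and exponentiated, so a
#' `linear_up` gene with `effect_size = 1` doubles in expression across the
#' sampled lifespan, and `midlife_peak`/`wave` genes return exactly to their
#' baseline at the final day (equal first/last expected means — the genes a
#' two-timepoint young-versus-old contrast is structurally blind to).
#'
#' @param n_genes Number of genes.
#' @param class_mix Named proportions over [trajectory_classes()]; must sum
#'   to 1. Class counts are deterministic (largest-remainder rounding).
#' @param baseline_range Baseline normalized means are drawn log-uniformly
#'   from this range.
#' @param effect_size Log2 amplitude of non-null trajectories: a single
#'   number or a `function(n)` returning `n` draws.
#' @param dispersion NB dispersion (`Var = mu + alpha * mu^2`): single
#'   number or `function(n)`.
#' @param days Sampling days defining the trajectory support.
#' @param seed Integer seed; identical arguments and seed give identical
#'   truth tables.
#' @return Object of class `trajectory_truth`: list with `genes` (data.frame
#'   of `gene_id`, `traj_class`, `baseline_mean`, `effect_size`,
#'   `dispersion`), `mean_matrix` (genes x sampling points, expected
#'   normalized means, columns `SP1..SPn`) and `days`.
#' @export
#' @examples
#' tr <- make_truth(100, class_mix = c(null = 1), seed = 1)
#' all(apply(tr$mean_matrix, 1, stats::sd) == 0)
make_truth <- function(n_genes,
                       class_mix = c(null = 0.5, linear_up = 0.2,
                                     linear_down = 0.2, midlife_peak = 0.05,
                                     wave = 0.05),
                       baseline_range = c(20, 2000),
                       effect_size = 1,
                       dispersion = 0.05,
                       days = default_sampling_days(),
                       seed = NULL) {
  if (any(class_mix < 0)) stop("parameter error: class proportions must be non-negative")
  if (abs(sum(class_mix) - 1) > 1e-9) stop("parameter error: class proportions must sum to 1")
  if (is.null(names(class_mix)) || !all(names(class_mix) %in% trajectory_classes())) {
    stop("parameter error: 'class_mix' must be named with trajectory classes")
  }
  if (!is.null(seed)) set.seed(seed)

  counts <- round_class_counts(n_genes, class_mix)
  classes <- rep(names(class_mix), counts)

  draw <- function(x, n) if (is.function(x)) x(n) else rep(x, length.out = n)
  baseline <- exp(stats::runif(n_genes, log(baseline_range[1]),
                               log(baseline_range[2])))
  eff <- draw(effect_size, n_genes)
  eff[classes == "null"] <- 0
  alpha <- draw(dispersion, n_genes)
  if (any(alpha < 0)) stop("parameter error: dispersion must be non-negative")

  u <- if (length(days) > 1L) (days - min(days)) / (max(days) - min(days)) else 0
  tmpl <- vapply(seq_len(n_genes), function(g) {
    trajectory_template(classes[g], u, eff[g])
  }, numeric(length(days)))
  log2mat <- if (length(days) == 1L) matrix(tmpl, ncol = 1L) else t(tmpl)
  mean_matrix <- baseline * 2^log2mat
  gene_id <- sprintf("g%05d", seq_len(n_genes))
  dimnames(mean_matrix) <- list(gene_id, sprintf("SP%d", seq_along(days)))

  structure(
    list(
      genes = data.frame(gene_id = gene_id, traj_class = classes,
                         baseline_mean = baseline, effect_size = eff,
                         dispersion = alpha, stringsAsFactors = FALSE),
      mean_matrix = mean_matrix,
      days = days
    ),
    class = "trajectory_truth"
  )
}

#' @export
print.trajectory_truth <- function(x, ...) {
  cat("trajectory_truth:", nrow(x$genes), "genes,",
      length(x$days), "sampling days\n")
  print(table(x$genes$traj_class))
  invisible(x)
}

#' Simulate a negative-binomial count matrix from trajectory truth
#'
#' Draws one library-size factor per sample (log-uniform) and, for each gene
#' and sample, a negative-binomial count with mean
#' `size_factor * mean_function(sampling point)` and the gene's dispersion
#' (`Var = mu + alpha * mu^2`; `alpha = 0` gives Poisson counts).
#'
#' @param truth A `trajectory_truth` object from [make_truth()].
#' @param design Sample table from [make_design()]; its sampling-point
#'   levels must match the truth's mean-matrix columns.
#' @param size_factor_range Range `(lo, hi)`, `lo > 0`, for the log-uniform
#'   size factors.
#' @param seed Integer seed.
#' @return Integer matrix genes x samples with `dimnames`, and the drawn
#'   size factors in `attr(, "size_factors")` for recovery tests.
#' @export
#' @examples
#' tr <- make_truth(50, seed = 1)
#' counts <- simulate_counts(tr, make_design(), seed = 1)
#' dim(counts)
simulate_counts <- function(truth, design, size_factor_range = c(0.5, 2),
                            seed = NULL) {
  if (!inherits(truth, "trajectory_truth")) stop("input error: 'truth' must come from make_truth()")
  if (nrow(truth$genes) == 0L || nrow(design) == 0L) {
    stop("input error: empty truth or design")
  }
  if (size_factor_range[1] <= 0 || size_factor_range[2] < size_factor_range[1]) {
    stop("parameter error: invalid size factor range")
  }
  sp <- as.character(design$sampling_point)
  if (!all(sp %in% colnames(truth$mean_matrix))) {
    stop("input error: design sampling points not covered by truth")
  }
  if (!is.null(seed)) set.seed(seed)

  n_s <- nrow(design)
  n_g <- nrow(truth$genes)
  s <- exp(stats::runif(n_s, log(size_factor_range[1]),
                        log(size_factor_range[2])))
  names(s) <- design$sample_id

  mu <- truth$mean_matrix[, sp, drop = FALSE] *
    rep(s, each = n_g)
  alpha <- truth$genes$dispersion
  counts <- matrix(0L, n_g, n_s,
                   dimnames = list(truth$genes$gene_id, design$sample_id))
  pois <- alpha < 1e-12
  if (any(pois)) {
    counts[pois, ] <- stats::rpois(sum(pois) * n_s, lambda = mu[pois, ])
  }
  if (any(!pois)) {
    m <- mu[!pois, , drop = FALSE]
    counts[!pois, ] <- stats::rnbinom(sum(!pois) * n_s, mu = m,
                                      size = rep(1 / alpha[!pois], n_s))
  }
  storage.mode(counts) <- "integer"
  attr(counts, "size_factors") <- s
  counts
}
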