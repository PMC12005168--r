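# Independent oracles used across tests. These deliberately re-derive
# results by brute force / enumeration, never by calling the code paths
# they check.

# BH step-up adjusted p-values computed naively per element from the
# definition: adj_i = min over ranks k >= rank(i) of n * p_(k) / k.
brute_force_bh <- function(p) {
  n <- length(p)
  s <- sort(p)
  vapply(p, function(pi) {
    ri <- sum(s <= pi)
    min(1, min(n * s[ri:n] / (ri:n)))
  }, numeric(1))
}

# Upper-tail hypergeometric P(X >= x) by exhaustive enumeration of all
# n-subsets of an N-element universe containing a fixed K-element set.
enum_hyper_tail <- function(N, K, n, x) {
  subs <- utils::combn(N, n)
  overlaps <- colSums(subs <= K)
  mean(overlaps >= x)
}

# Naive O(n^3) agglomerative clustering via Lance-Williams updates;
# returns the sorted merge heights.
naive_linkage_heights <- function(d, method = c("complete", "average", "ward")) {
  method <- match.arg(method)
  d <- as.matrix(d)
  n <- nrow(d)
  diag(d) <- Inf
  sizes <- rep(1, n)
  active <- rep(TRUE, n)
  heights <- numeric(n - 1)
  for (m in seq_len(n - 1)) {
    dd <- d
    dd[!active, ] <- Inf
    dd[, !active] <- Inf
    ij <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    h <- d[i, j]
    heights[m] <- h
    for (k in which(active)) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <- switch(method,
        complete = max(d[i, k], d[j, k]),
        average = (sizes[i] * d[i, k] + sizes[j] * d[j, k]) /
          (sizes[i] + sizes[j]),
        ward = sqrt(((sizes[i] + sizes[k]) * d[i, k]^2 +
                       (sizes[j] + sizes[k]) * d[j, k]^2 -
                       sizes[k] * h^2) /
                      (sizes[i] + sizes[j] + sizes[k]))
      )
    }
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
    d[j, ] <- d[, j] <- Inf
  }
  sort(heights)
}

# Standardized z-scale archetype trajectories of the four non-null classes
# on the default sampling days (matching the generator's templates).
archetype_z <- function(days = default_sampling_days()) {
  u <- (days - min(days)) / (max(days) - min(days))
  du <- u - mean(u)
  phi <- atan2(-sum(du * sin(2 * pi * u)), sum(du * cos(2 * pi * u)))
  arch <- rbind(
    linear_up = u,
    linear_down = -u,
    midlife_peak = (1 - cos(2 * pi * u)) / 2,
    wave = sin(2 * pi * u + phi) / 2
  )
  t(apply(arch, 1, function(x) (x - mean(x)) / stats::sd(x)))
}

# Noisy gene-level z matrix from the archetypes: `per_class` genes each.
archetype_mixture <- function(per_class = 25, noise_sd = 0.3,
                              days = default_sampling_days()) {
  arch <- archetype_z(days)
  z <- arch[rep(1:4, each = per_class), ] +
    matrix(stats::rnorm(4 * per_class * length(days), sd = noise_sd),
           4 * per_class)
  rownames(z) <- sprintf("g%04d", seq_len(nrow(z)))
  structure(z, class = c("trajectory_matrix", "matrix", "array"),
            truth_class = rep(rownames(arch), each = per_class))
}

# Small fixture: simulated cohort with the default design.
sim_cohort <- function(n_genes = 400, class_mix = c(null = 0.5,
                                                    linear_up = 0.2,
                                                    linear_down = 0.2,
                                                    midlife_peak = 0.05,
                                                    wave = 0.05),
                       dispersion = 0.05, effect_size = 1, seed = 1) {
  design <- make_design()
  truth <- make_truth(n_genes, class_mix = class_mix,
                      effect_size = effect_size, dispersion = dispersion,
                      seed = seed)
  counts <- simulate_counts(truth, design, seed = seed + 10000L)
  list(design = design, truth = truth, counts = counts)
}
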