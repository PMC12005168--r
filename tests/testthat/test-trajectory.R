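make_tiny_samples <- function(days, reps) {
  make_design(days = days, replicates = reps)
}

test_that("Z-score trajectories match the hand-computed two-point example", {
  s <- make_tiny_samples(c(10, 20), c(1, 1))
  m <- matrix(c(1, 3), 1, 2, dimnames = list("g1", s$sample_id))
  z <- zscore_trajectories(m, s)
  expect_equal(unname(z[1, ]), c(-1 / sqrt(2), 1 / sqrt(2)))
})

test_that("the replicate-weighted mean of every Z row is zero, including unbalanced designs", {
  sim <- sim_cohort(n_genes = 150, seed = 31)
  norm <- normalize_counts(sim$counts)
  z <- zscore_trajectories(norm, sim$design)
  w <- attr(z, "replicates")
  weighted <- as.vector(unclass(z) %*% w) / sum(w)
  expect_lt(max(abs(weighted)), 1e-9)
  # balanced design: the simple mean is also zero
  bal <- make_tiny_samples(c(3, 10, 20, 30), rep(2L, 4))
  tr <- make_truth(20, days = bal$day[!duplicated(bal$day)], seed = 32)
  cts <- simulate_counts(tr, bal, seed = 33)
  zb <- zscore_trajectories(normalize_counts(cts), bal)
  expect_lt(max(abs(rowMeans(unclass(zb)))), 1e-9)
})

test_that("constant-expression genes are excluded with a warning", {
  s <- make_tiny_samples(c(10, 20), c(2, 2))
  m <- rbind(g1 = c(1, 1, 1, 1), g2 = c(1, 2, 3, 4))
  colnames(m) <- s$sample_id
  expect_warning(z <- zscore_trajectories(m, s), "excluded")
  expect_equal(rownames(z), "g2")
  expect_equal(attr(z, "excluded"), "g1")
})

test_that("Pearson dissimilarity has the documented geometry", {
  z <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(-1, -2, -3),
             d = c(1, 3, 2))
  d <- pearson_dissimilarity(z)
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 2)
  expect_equal(d["a", "d"], 0.5)  # r = 0.5 by hand
  expect_true(isSymmetric(d))
  expect_error(pearson_dissimilarity(rbind(a = c(1, 1, 1), b = 1:3)),
               "constant")
  expect_error(pearson_dissimilarity(z[, 1:2]), "3 sampling points")
})

test_that("hierarchical clustering reproduces the hand-worked 3-point agglomeration", {
  d <- matrix(c(0, 1, 5, 1, 0, 6, 5, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- hierarchical_cluster(d, "complete")
  expect_equal(hc$height, c(1, 6))
  asg <- cut_clusters(hc, 2)
  expect_equal(asg$cluster[["A"]], asg$cluster[["B"]])
  expect_false(asg$cluster[["A"]] == asg$cluster[["C"]])
  # n = 2: a single merge at the pairwise distance
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(hierarchical_cluster(d2)$height, 0.3)
  d_na <- d
  d_na[1, 2] <- d_na[2, 1] <- NA
  expect_error(hierarchical_cluster(d_na), "input error")
})

test_that("merge heights equal a naive O(n^3) agglomeration for all linkages", {
  set.seed(41)
  for (rep in 1:15) {
    n <- sample(4:30, 1)
    x <- matrix(rnorm(n * 8), n)
    d <- as.matrix(dist(x))
    for (link in c("complete", "average", "ward")) {
      hc <- hierarchical_cluster(d, link)
      expect_equal(sort(hc$height), naive_linkage_heights(d, link),
                   tolerance = 1e-8)
    }
  }
})

test_that("cutting the tree respects k and canonical dendrogram-order labels", {
  set.seed(42)
  z <- archetype_mixture(per_class = 10)
  hc <- hierarchical_cluster(pearson_dissimilarity(z))
  expect_error(cut_clusters(hc, 0), "parameter error")
  expect_error(cut_clusters(hc, 41), "parameter error")
  all1 <- cut_clusters(hc, 1)
  expect_equal(all1$sizes, 40L)
  sing <- cut_clusters(hc, 40)
  expect_equal(sort(unname(sing$cluster)), 1:40)
  a4 <- cut_clusters(hc, 4)
  expect_equal(sum(a4$sizes), 40L)
  # labels are 1..k in leaf order: first leaf belongs to cluster 1
  expect_equal(unname(a4$cluster[hc$order[1]]), 1L)
  expect_equal(unname(a4$cluster[hc$order[40]]), 4L)
})

test_that("cluster assignment is invariant to gene input order", {
  set.seed(43)
  z <- archetype_mixture(per_class = 8)
  perm <- sample(nrow(z))
  a1 <- cut_clusters(hierarchical_cluster(pearson_dissimilarity(z)), 4)
  zp <- unclass(z)[perm, ]
  a2 <- cut_clusters(hierarchical_cluster(pearson_dissimilarity(zp)), 4)
  expect_equal(a1$cluster[rownames(z)], a2$cluster[rownames(z)])
})

test_that("scan_k reports size-band violations and recommends a compliant k", {
  set.seed(44)
  z <- archetype_mixture(per_class = 25)
  hc <- hierarchical_cluster(pearson_dissimilarity(z))
  tab <- scan_k(hc, size_band = c(1, 100), k_range = 2:6)
  expect_true(all(tab$n_outside_band == 0))
  tab2 <- scan_k(hc, size_band = c(10, 40), k_range = 2:10)
  expect_equal(attr(tab2, "recommended_k"), 4L)
  asg <- cut_clusters(hc, 4)
  truth <- attr(z, "truth_class")
  # purity of the recommended cut against the construction
  purity <- mean(vapply(1:4, function(i) {
    max(table(truth[asg$cluster == i])) / sum(asg$cluster == i)
  }, numeric(1)))
  expect_gte(purity, 0.95)
  expect_error(scan_k(hc, c(40, 10), 2:4), "parameter error")
  expect_error(scan_k(hc, c(10, 40), integer()), "parameter error")
})
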