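test_that("GMT parsing de-duplicates members, errors on short lines, and round-trips", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc one\tg1\tg2\tg2", "S2\tdesc two\tg3"), f)
  coll <- read_gmt(f)
  expect_equal(coll$sets$S1$genes, c("g1", "g2"))
  expect_equal(coll$sets$S2$genes, "g3")
  f2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, f2)
  coll2 <- read_gmt(f2, name = coll$name)
  expect_equal(coll2, coll)
  fbad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tg1", "S2\tonlydesc"), fbad)
  expect_error(read_gmt(fbad), "line 2")
  fe <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(), fe)
  expect_warning(ce <- read_gmt(fe), "empty")
  expect_length(ce$sets, 0)
})

test_that("hypergeometric tail matches direct combinatorics and exhaustive enumeration", {
  universe <- sprintf("u%02d", 1:10)
  h <- hypergeom_enrich(universe[1:5], universe[1:5], universe)
  expect_equal(h$p_value, 1 / choose(10, 5))
  h0 <- hypergeom_enrich(universe[6:10], universe[1:5], universe)
  expect_equal(h0$p_value, 1)  # x = 0 => P(X >= 0) = 1
  expect_error(hypergeom_enrich("a", "a", character()), "empty background")
  # exhaustive-enumeration oracle over N <= 12 configurations, at every
  # achievable overlap x (cluster built to contain exactly x set members)
  for (N in c(5, 8, 12)) {
    uni <- sprintf("n%02d", 1:N)
    for (K in c(0, 2, N %/% 2, N)) {
      for (n in c(1, N %/% 2, N)) {
        for (x in max(0, n - (N - K)):min(n, K)) {
          cl <- uni[c(seq_len(x), K + seq_len(n - x))]
          p_pkg <- hypergeom_enrich(cl, uni[seq_len(K)], uni)
          expect_equal(p_pkg$x, x)
          expect_equal(p_pkg$p_value, enum_hyper_tail(N, K, n, x),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("hypergeometric tail equals enumeration for random configurations", {
  set.seed(71)
  for (i in 1:25) {
    N <- sample(4:12, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    uni <- sprintf("m%02d", 1:N)
    cl <- sample(uni, n)
    gs <- uni[seq_len(K)]
    x <- length(intersect(cl, gs))
    p_pkg <- hypergeom_enrich(cl, gs, uni)$p_value
    expect_equal(p_pkg, enum_hyper_tail(N, K, n, x), tolerance = 1e-12)
  }
})

test_that("a planted set dominates its cluster's enrichment table", {
  set.seed(72)
  background <- sprintf("g%04d", 1:1000)
  planted <- background[1:30]
  cluster <- c(planted, sample(background[31:1000], 30))
  other_sets <- lapply(1:20, function(i) {
    list(description = paste("random", i), genes = sample(background, 25))
  })
  names(other_sets) <- sprintf("R%02d", 1:20)
  coll <- structure(list(name = "toy",
                         sets = c(list(planted = list(description = "planted",
                                                      genes = planted)),
                                  other_sets)),
                    class = "gene_set_collection")
  et <- enrich_all(list(c1 = cluster), coll, background)
  top <- et[which.min(et$p_value), ]
  expect_equal(top$set_id, "planted")
  expect_lt(top$p_value, 1e-20)
  expect_true(top$significant)
  expect_equal(top$x, 30L)
  expect_equal(top$fold_enrichment, (30 / 60) / (30 / 1000))
})

test_that("BH scoping is per (cluster, collection) and identical collections give identical tables", {
  set.seed(73)
  background <- sprintf("g%04d", 1:500)
  clusters <- list(a = sample(background, 40), b = sample(background, 60))
  sets <- lapply(1:15, function(i) {
    list(description = "s", genes = sample(background, 20))
  })
  names(sets) <- sprintf("S%02d", 1:15)
  coll1 <- structure(list(name = "c1", sets = sets),
                     class = "gene_set_collection")
  coll2 <- structure(list(name = "c2", sets = sets),
                     class = "gene_set_collection")
  et <- enrich_all(clusters, list(coll1, coll2), background)
  # each (cluster, collection) block's adjusted p depends only on its own rows
  for (cl in names(clusters)) {
    for (co in c("c1", "c2")) {
      block <- et[et$cluster == cl & et$collection == co, ]
      expect_equal(block$adjusted_p, bh_adjust(block$p_value))
    }
  }
  sub1 <- et[et$collection == "c1", setdiff(names(et), "collection")]
  sub2 <- et[et$collection == "c2", setdiff(names(et), "collection")]
  rownames(sub1) <- rownames(sub2) <- NULL
  expect_equal(sub1, sub2)
})

test_that("null enrichment with random clusters is calibrated", {
  set.seed(74)
  background <- sprintf("g%04d", 1:2000)
  sets <- lapply(1:100, function(i) {
    list(description = "s", genes = sample(background, 40))
  })
  names(sets) <- sprintf("S%03d", 1:100)
  coll <- structure(list(name = "null", sets = sets),
                    class = "gene_set_collection")
  sig_frac <- replicate(10, {
    cl <- list(c1 = sample(background, 80))
    mean(enrich_all(cl, coll, background)$significant)
  })
  # BH at 0.05 over near-null tests: significant fraction stays near zero
  expect_lt(mean(sig_frac), 0.05 + 3 * stats::sd(sig_frac) / sqrt(10) + 0.02)
})

test_that("empty-background sets are dropped with a warning and oversized clusters error", {
  background <- sprintf("g%03d", 1:50)
  coll <- structure(list(name = "c",
                         sets = list(inA = list(description = "", genes = background[1:5]),
                                     out = list(description = "", genes = "absent"))),
                    class = "gene_set_collection")
  expect_warning(et <- enrich_all(list(k = background[1:10]), coll, background),
                 "dropped")
  expect_equal(unique(et$set_id), "inA")
  expect_error(enrich_all(list(k = c(background, "extra")), coll, background),
               "smaller than a cluster")
})
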