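test_that("PCA symmetry, spectral ordering, and rank guard", {
  set.seed(20)
  G <- matrix(rbinom(200 * 8, 2, 0.3), 200, 8)
  G[, 2] <- G[, 1]                       # identical pair
  dip <- dipset("c", 1:200, G, paste0("s", 1:8))
  p <- pca_genotypes(dip, n_components = 4)
  expect_equal(p$coords[1, ], p$coords[2, ])
  expect_true(all(diff(p$explained_var) <= 1e-12))
  expect_lte(sum(p$explained_var), 1 + 1e-12)
  expect_error(pca_genotypes(dip, n_components = 50), "rank")
})

test_that("strong regional differentiation separates regions on PC1", {
  sim <- simulate_cohorts(sim_design(n_per_cell = 20, rounds = "baseline",
                                     arms = "PBO",
                                     n_sites = c("2RL" = 2000),
                                     d = 5, sigma_h = 0, seed = 22))
  dip <- hap_to_dip(sim$sets[["2RL"]])
  p <- pca_genotypes(dip, n_components = 2)
  sil <- silhouette_1d(p$coords[, 1],
                       sim$frame$region[match(rownames(p$coords),
                                              sim$frame$sample_id)])
  expect_gt(sil, 0.8)
})

test_that("Manhattan distances match direct summation and the metric axioms", {
  d <- manhattan_dist(dipset("c", 1:3, cbind(c(0, 1, 2), c(2, 1, 0)),
                             c("a", "b")))
  expect_equal(d["a", "b"], 4)
  expect_equal(unname(diag(d)), c(0, 0))

  set.seed(21)
  for (rep in 1:5) {
    G <- matrix(sample(c(0:2, NA), 30 * 8, replace = TRUE,
                       prob = c(.3, .3, .3, .1)), 30, 8)
    dip <- dipset("c", 1:30, G, paste0("s", 1:8))
    D <- manhattan_dist(dip)
    expect_equal(unname(D), oracle_manhattan(G))
    expect_equal(D, t(D))
    for (i in 1:8) for (j in 1:8) for (k in 1:8)
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-9)
  }
  G <- cbind(c(0, NA), c(NA, 1))
  expect_error(manhattan_dist(dipset("c", 1:2, G, c("a", "b"))),
               "share no non-missing site")
})

test_that("neighbour joining solves the 3-taxon closed form", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- nj_tree(D)
  tips <- tree$edge[, 2] <= 3
  bl <- setNames(tree$edge.length[tips],
                 tree$tip.label[tree$edge[tips, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), ">= 3 taxa")
  Dbad <- D; Dbad[1, 2] <- 5
  expect_error(nj_tree(Dbad), "not symmetric")
})

test_that("NJ recovers random additive trees exactly", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    true <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
    true <- ape::unroot(true)
    D <- cophenetic(true)
    est <- nj_tree(D)
    expect_equal(ape::dist.topo(est, true)[1], 0)
    expect_equal(cophenetic(est)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
    # Newick round-trip preserves the tree
    rt <- ape::read.tree(text = ape::write.tree(est))
    expect_equal(ape::dist.topo(rt, est)[1], 0)
  }
})

test_that("F_ST estimators reproduce their per-site formulas", {
  # fixed difference
  for (est in c("hudson", "patterson"))
    expect_equal(fst_estimate(list(p = 1, n = 10), list(p = 0, n = 10),
                              est)$fst, 1)
  # hudson plug-in: p1 = p2 = 0.5, n = 6 -> N = -0.1, D = 0.5
  r <- fst_estimate(list(p = 0.5, n = 6), list(p = 0.5, n = 6), "hudson")
  expect_equal(r$num, -0.1)
  expect_equal(r$den, 0.5)
  expect_equal(r$fst, -0.2)
  # identical populations at infinite n -> 0 (patterson)
  r2 <- fst_estimate(list(p = rep(0.4, 50), n = rep(1e7, 50)),
                     list(p = rep(0.4, 50), n = rep(1e7, 50)), "patterson")
  expect_equal(r2$fst, 0, tolerance = 1e-5)
})

test_that("F_ST is symmetric, relabel-invariant, and excludes 0/0 sites", {
  set.seed(24)
  pA <- runif(300); pB <- runif(300)
  a <- list(p = c(pA, 0, 1), n = rep(40, 302))
  b <- list(p = c(pB, 0, 1), n = rep(40, 302))
  for (est in c("hudson", "patterson")) {
    f_ab <- fst_estimate(a, b, est)
    f_ba <- fst_estimate(b, a, est)
    expect_equal(f_ab$fst, f_ba$fst)
    expect_equal(f_ab$n_sites_used, 300L)  # both-monomorphic excluded
    flip <- fst_estimate(list(p = 1 - a$p, n = a$n),
                         list(p = 1 - b$p, n = b$n), est)
    expect_equal(f_ab$fst, flip$fst, tolerance = 1e-12)
  }
})

test_that("Hudson and Patterson agree on simulated demes", {
  sim <- simulate_cohorts(sim_design(n_per_cell = 100, rounds = "baseline",
                                     arms = "PBO",
                                     n_sites = c("2RL" = 2000),
                                     d = 0.5, sigma_h = 0, seed = 25))
  hap <- sim$sets[["2RL"]]
  east <- subset_samples(hap, sim$frame$sample_id[sim$frame$region == "East"])
  west <- subset_samples(hap, sim$frame$sample_id[sim$frame$region == "West"])
  fh <- fst_estimate(east, west, "hudson")$fst
  fp <- fst_estimate(east, west, "patterson")$fst
  expect_gt(fh, 0.005)
  expect_lt(abs(fh - fp), 0.01)
})

test_that("Mann-Whitney U matches enumeration and its approximation", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p, 0.99)
  set.seed(26)
  for (rep in 1:10) {
    x <- rnorm(8); y <- rnorm(8)
    exact <- wilcox.test(x, y, exact = TRUE)$p.value
    approx <- wilcox.test(x, y, exact = FALSE)$p.value
    expect_lt(abs(exact - approx), 0.02)
    expect_equal(mann_whitney_u(x, y)$p, exact)
  }
})

test_that("the two-individual resampling null is seeded and detects divergence", {
  sim <- simulate_cohorts(sim_design(n_per_cell = 15, rounds = "baseline",
                                     arms = "PBO",
                                     n_sites = c("2RL" = 1500),
                                     d = 3, sigma_h = 0, seed = 27))
  dip <- hap_to_dip(sim$sets[["2RL"]])
  ids_a <- sim$frame$sample_id[sim$frame$region == "East"]
  ids_b <- sim$frame$sample_id[sim$frame$region == "West"]
  n1 <- fst_resampling_null(dip, ids_a, ids_b, n_snps = 500,
                            n_iter = 120, seed = 7)
  n2 <- fst_resampling_null(dip, ids_a, ids_b, n_snps = 500,
                            n_iter = 120, seed = 7)
  expect_identical(n1$between, n2$between)
  expect_lt(n1$mw_a$p, 0.001)
  expect_lt(n1$mw_b$p, 0.001)
  expect_gt(median(n1$between), median(n1$within_a))
  expect_error(fst_resampling_null(dip, ids_a[1], ids_b, n_snps = 10,
                                   n_iter = 5), ">= 2 individuals")
})
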