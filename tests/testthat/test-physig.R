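test_that("the VCV matches hand traversal and is PSD on random trees", {
  C <- phylo_vcv(hand_tree())
  expect_equal(unname(C), unname(hand_vcv()))
  tr <- star_tree(5)
  expect_equal(unname(phylo_vcv(tr)), diag(5), ignore_attr = TRUE)
  set.seed(4)
  for (i in 1:5) {
    C <- phylo_vcv(ape::rtree(10))
    expect_equal(C, t(C))
    expect_gt(min(eigen(C, symmetric = TRUE)$values), -1e-10)
  }
})

test_that("K equals 1 exactly on a star tree for any trait vector", {
  tr <- star_tree(16)
  set.seed(5)
  for (i in 1:20) {
    x <- stats::setNames(rnorm(16), tr$tip.label)
    expect_equal(blomberg_k(tr, x)$K, 1, tolerance = 1e-12)
  }
})

test_that("K agrees with a naive explicit-inverse implementation to 1e-10", {
  set.seed(61)
  for (i in 1:10) {
    tr <- ape::rtree(8)
    x <- stats::setNames(rnorm(8), tr$tip.label)
    got <- blomberg_k(tr, x)$K
    expect_equal(got, naive_blomberg_k(phylo_vcv(tr), x[tr$tip.label]),
                 tolerance = 1e-10)
  }
})

test_that("K agrees with the picante reference implementation", {
  skip_if_not_installed("picante")
  set.seed(62)
  for (i in 1:5) {
    tr <- ape::rtree(12)
    x <- stats::setNames(rnorm(12), tr$tip.label)
    expect_equal(blomberg_k(tr, x)$K,
                 as.numeric(picante::Kcalc(x[tr$tip.label], tr)),
                 tolerance = 1e-8)
  }
})

test_that("K is invariant to affine trait transforms and branch rescaling", {
  set.seed(63)
  tr <- ape::rtree(10)
  x <- stats::setNames(rnorm(10), tr$tip.label)
  k0 <- blomberg_k(tr, x)$K
  expect_equal(blomberg_k(tr, 3 * x + 7)$K, k0, tolerance = 1e-10)
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 13
  expect_equal(blomberg_k(tr2, x)$K, k0, tolerance = 1e-10)
})

test_that("white noise on an imbalanced tree gives K below 1 on average", {
  set.seed(64)
  tr <- ape::rtree(32)
  ks <- replicate(200, {
    x <- stats::setNames(rnorm(32), tr$tip.label)
    blomberg_k(tr, x)$K
  })
  expect_lt(mean(ks), 0.9)
})

test_that("degenerate K inputs raise the documented errors", {
  tr <- star_tree(4)
  x <- stats::setNames(rep(1, 4), tr$tip.label)
  expect_error(blomberg_k(tr, x), "zero trait variance")
  expect_error(blomberg_k(tr, c(a = 1, b = 2)), "cover every tip")
})

test_that("the permutation null on a star tree is exchangeable: p = 1", {
  tr <- star_tree(8)
  x <- stats::setNames(rnorm(8), tr$tip.label)
  res <- permutation_test_k(tr, x, n_perm = 99, seed = 1)
  expect_equal(res$p_value, 1)
  expect_equal(stats::var(res$null_K), 0, tolerance = 1e-20)
})

test_that("permutation p-values are reproducible and land on the 1/(n+1) grid", {
  set.seed(65)
  tr <- ape::rtree(16)
  x <- simulate_bm(tr, 1, 0)
  r1 <- permutation_test_k(tr, x, n_perm = 999, seed = 42)
  r2 <- permutation_test_k(tr, x, n_perm = 999, seed = 42)
  expect_identical(r1$K, r2$K)
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(r1$p_value * 1000, round(r1$p_value * 1000), tolerance = 1e-9)
  expect_error(permutation_test_k(tr, x, n_perm = 0), "n_perm")
})

test_that("strong planted signal is detected by the permutation test", {
  set.seed(66)
  tr <- ape::rtree(32)
  hits <- 0L
  for (i in 1:20) {
    x <- simulate_bm(tr, 1, 0)
    p <- permutation_test_k(tr, x, n_perm = 199)$p_value
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / 20, 0.9)
})

test_that("per-trait signal table collapses replicates to species means", {
  cfg <- synthetic_config(seed = 31, signal_lambda = c(LTPC = 1),
                          species_sd = 1, noise_sd = 0.1)
  ds <- generate_dataset(cfg)
  out <- phylo_signal_all(ds$traits, ds$tree, n_perm = 99, seed = 42)
  expect_equal(nrow(out), 26L)
  expect_true(all(out$K > 0))
  out2 <- phylo_signal_all(ds$traits, ds$tree, n_perm = 99, seed = 42)
  expect_identical(out$K, out2$K)
  expect_identical(out$p_value, out2$p_value)
})
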