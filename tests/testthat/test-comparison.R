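test_that("normality gate passes Gaussian samples and rejects exponential ones", {
  set.seed(31)
  pass <- replicate(200, normality_gate(rnorm(50), rnorm(50)))
  expect_equal(mean(pass), (1 - 0.05)^2, tolerance = 0.06)
  set.seed(32)
  expect_false(normality_gate(rexp(200), rnorm(200)))
  expect_warning(gate <- normality_gate(c(1, 2), rnorm(10)), "n < 3")
  expect_false(gate)
})

test_that("identical groups give p = 1 under the Mann-Whitney branch", {
  ds <- generate_dataset(null_config(1))
  tab <- ds$traits
  tab$LC <- rep(rep(c(1, 2, 3), length.out = 36), 2)  # heavy ties -> MW
  res <- compare_trait("LC", tab)
  expect_equal(res$chosen_test, "mann_whitney")
  expect_equal(res$p_value, 1, tolerance = 1e-9)
})

test_that("a planted offset of 2 noise sd is detected with high power", {
  hits <- 0L
  for (seed in 1:40) {
    cfg <- synthetic_config(seed = seed, species_sd = 0,
                            n_replicates = 8L,  # 32 samples per group
                            type_offsets = c(LTPC = 2), noise_sd = 1)
    ds <- generate_dataset(cfg)
    res <- compare_trait("LTPC", ds$traits)
    hits <- hits + (res$p_value < 0.05 &&
                      res$direction == "ephemeral")
  }
  expect_gt(hits / 40, 0.9)
})

test_that("Mann-Whitney statistic is invariant under monotone transforms", {
  set.seed(7)
  ds <- generate_dataset(null_config(7))
  tab <- ds$traits
  tab$SLA <- rexp(nrow(tab))  # guarantees the MW branch
  r1 <- compare_trait("SLA", tab)
  tab2 <- tab; tab2$SLA <- log(tab2$SLA)
  r2 <- compare_trait("SLA", tab2)
  expect_equal(r1$chosen_test, "mann_whitney")
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("standardization has the defining properties", {
  ds <- generate_dataset(synthetic_config(seed = 13))
  z <- standardize_traits(ds$traits)
  expect_equal(unname(colMeans(z)), rep(0, ncol(z)), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, ncol(z)), tolerance = 1e-12)
  z2 <- standardize_traits(z)
  expect_equal(z2[, 1], z[, 1], tolerance = 1e-12, ignore_attr = TRUE)
  tab <- ds$traits; tab$LC <- 5
  expect_warning(z3 <- standardize_traits(tab), "LC")
  expect_false("LC" %in% colnames(z3))
})

test_that("PCA satisfies the spectral identities", {
  ds <- generate_dataset(synthetic_config(seed = 29,
    module_spec = list(m = c("LC", "LN", "LP")), module_rho = 0.9))
  z <- standardize_traits(ds$traits)
  pc <- trait_pca(z)
  expect_equal(sum(pc$variance_explained), 1, tolerance = 1e-12)
  expect_true(all(diff(pc$variance_explained) < 1e-12))
  # orthonormal loadings, decorrelated scores
  expect_equal(crossprod(pc$loadings), diag(ncol(pc$loadings)),
               tolerance = 1e-8, ignore_attr = TRUE)
  cv <- stats::cov(pc$scores)
  expect_equal(cv[upper.tri(cv)], rep(0, sum(upper.tri(cv))),
               tolerance = 1e-8)
  # reconstruction from all components
  zc <- scale(z[stats::complete.cases(z), , drop = FALSE])
  rec <- pc$scores %*% t(pc$loadings)
  expect_equal(unname(rec), unname(zc[, colnames(z)]), tolerance = 1e-8)
  # sign convention
  for (j in seq_len(ncol(pc$loadings))) {
    v <- pc$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("two perfectly correlated traits load entirely on PC1", {
  x <- rnorm(40)
  z <- scale(cbind(a = x, b = 2 * x + 3))
  pc <- trait_pca(z)
  expect_equal(pc$variance_explained[1], 1, tolerance = 1e-12)
})
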