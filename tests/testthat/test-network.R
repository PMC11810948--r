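test_that("Spearman matrix reproduces hand-computed coefficients", {
  x <- 1:5
  tab <- data.frame(a = x, b = c(1, 3, 2, 5, 4), c = -x, d = x^3)
  m <- as.matrix(tab)
  corr <- spearman_matrix(m, min_pairs = 5)
  expect_equal(corr$rho["a", "b"], 1 - 6 * 4 / (5 * 24))  # = 0.8
  expect_equal(corr$rho["a", "c"], -1)
  expect_equal(corr$rho["a", "d"], 1)   # monotone transform
  expect_equal(corr$rho, t(corr$rho))
  expect_equal(unname(diag(corr$rho)), rep(1, 4))
})

test_that("pairs below the minimum sample size are flagged missing", {
  m <- cbind(a = c(1, 2, 3, NA, NA, NA), b = c(2, 1, 3, NA, NA, NA),
             c = 1:6 + c(0.1, 0, 0.2, 0, 0.1, 0))
  corr <- spearman_matrix(m, min_pairs = 5)
  expect_true(is.na(corr$rho["a", "b"]))
  expect_equal(corr$n_pairs["a", "b"], 3)
  net <- binarize(corr, 0.2, 0.05)
  expect_equal(net$adjacency["a", "b"], 0L)
})

test_that("binarization applies strict thresholds on |rho| and p", {
  codes <- default_catalog()$code[1:3]
  rho <- matrix(c(1, 0.5, 0.20, 0.5, 1, -0.6, 0.20, -0.6, 1), 3, 3,
                dimnames = list(codes, codes))
  p <- matrix(c(0, 0.01, 0.001, 0.01, 0, 0.001, 0.001, 0.001, 0), 3, 3,
              dimnames = list(codes, codes))
  corr <- structure(list(rho = rho, p = p, n_pairs = rho * 0 + 50),
                    class = "correlation_matrices")
  net <- binarize(corr, r_threshold = 0.2, p_threshold = 0.05)
  expect_equal(net$adjacency[codes[1], codes[2]], 1L)  # clear edge
  expect_equal(net$adjacency[codes[1], codes[3]], 0L)  # |rho| not > 0.2
  expect_equal(net$adjacency[codes[2], codes[3]], 1L)  # negative edge counts
  expect_equal(unname(diag(net$adjacency)), rep(0L, 3))
})

test_that("complete-graph metrics are exact", {
  codes <- default_catalog()$code[1:4]
  A <- matrix(1L, 4, 4, dimnames = list(codes, codes)); diag(A) <- 0L
  net <- structure(list(adjacency = A,
                        nodes = data.frame(code = codes,
                                           category = "economic")),
                   class = "trait_network")
  met <- network_metrics(net)
  expect_equal(met$edge_density, 1)
  expect_equal(met$average_path_length, 1)
  expect_equal(met$modularity, 0)
  expect_equal(length(unique(met$modules)), 1L)
  expect_false(met$disconnected)
})

test_that("two disjoint K4 cliques recover the planted bipartition with Q = 0.5", {
  A <- matrix(0L, 8, 8)
  A[1:4, 1:4] <- 1L; A[5:8, 5:8] <- 1L; diag(A) <- 0L
  rownames(A) <- colnames(A) <- paste0("n", 1:8)
  g <- greedy_modularity(A)
  expect_equal(g$modularity, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(g$membership)), 2L)
  expect_equal(length(unique(g$membership[1:4])), 1L)
  expect_equal(length(unique(g$membership[5:8])), 1L)
  e <- exhaustive_modularity(A)
  expect_equal(e$modularity, 0.5, tolerance = 1e-12)
})

test_that("greedy modularity attains the exhaustive optimum on random graphs", {
  set.seed(314)
  for (i in 1:12) {
    A <- random_connected_graph(sample(4:8, 1))
    g <- greedy_modularity(A)
    e <- exhaustive_modularity(A)
    expect_gte(g$modularity + 1e-9, e$modularity)
    expect_equal(g$modularity, e$modularity, tolerance = 1e-9)
    expect_equal(g$modularity, modularity_q(A, g$membership),
                 tolerance = 1e-12)
  }
})

test_that("modularity of a partition agrees with the igraph reference", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (i in 1:5) {
    A <- random_connected_graph(7)
    memb <- sample(1:3, 7, replace = TRUE)
    ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(modularity_q(A, memb), igraph::modularity(ig, memb),
                 tolerance = 1e-12)
  }
})

test_that("degree sums, empty graphs and relative importance identities hold", {
  set.seed(100)
  A <- random_connected_graph(8)
  codes <- default_catalog()$code[1:8]
  rownames(A) <- colnames(A) <- codes
  nodes <- data.frame(code = codes,
                      category = default_catalog()$category[1:8])
  net <- structure(list(adjacency = A, nodes = nodes),
                   class = "trait_network")
  met <- network_metrics(net)
  expect_equal(sum(met$degree), 2 * met$n_edges)

  A0 <- matrix(0L, 26, 26,
               dimnames = list(default_catalog()$code,
                               default_catalog()$code))
  net0 <- structure(list(adjacency = A0,
                         nodes = default_catalog()[, c("code", "category")]),
                    class = "trait_network")
  expect_warning(met0 <- network_metrics(net0), "degrees are zero")
  expect_equal(met0$edge_density, 0)
  expect_equal(met0$modularity, 0)
  expect_true(is.na(met0$average_path_length))
  expect_true(all(met0$relative_importance == 0))
})

test_that("relative importance follows its defining formula", {
  cat26 <- default_catalog()
  deg <- stats::setNames(rep(2, 26), cat26$code)
  ri <- traitnet:::relative_importance_from_degree(
    deg, cat26[, c("code", "category")])
  expect_equal(unname(ri), rep(1 / 26, 3), tolerance = 1e-12)

  deg2 <- stats::setNames(rep(0, 26), cat26$code)
  deg2[cat26$code[cat26$category == "economic"][1]] <- 10
  ri2 <- traitnet:::relative_importance_from_degree(
    deg2, cat26[, c("code", "category")])
  expect_equal(unname(ri2["economic"]), (10 / 7) / 10, tolerance = 1e-12)
  expect_equal(unname(ri2["nutrient"]), 0)
  # scale invariance
  ri3 <- traitnet:::relative_importance_from_degree(
    deg2 * 2, cat26[, c("code", "category")])
  expect_equal(ri2, ri3, tolerance = 1e-12)
})

test_that("planted trait modules are recovered from synthetic data", {
  skip_if_not_installed("mclust")
  ds <- generate_dataset(module_config(seed = 10, rho = 0.85,
                                       n_replicates = 50L))
  net <- build_network(ds$traits)
  met <- network_metrics(net)
  cat26 <- default_catalog()
  planted <- as.integer(factor(cat26$category))[match(names(met$modules),
                                                      cat26$code)]
  ari <- mclust::adjustedRandIndex(met$modules, planted)
  expect_gt(ari, 0.8)
  # between-category false-edge rate under the |r|>0.2, p<0.05 rule
  ord <- match(rownames(net$adjacency), cat26$code)
  same <- outer(cat26$category[ord], cat26$category[ord], "==")
  between <- !same & upper.tri(same)
  expect_lte(mean(net$adjacency[between]), 0.07)
})

test_that("stratified networks respond to planted correlation strength", {
  d_hi <- generate_dataset(module_config(seed = 3, rho = 0.85,
                                         n_replicates = 25L))
  d_lo <- generate_dataset(synthetic_config(seed = 4, species_sd = 0,
                                            n_replicates = 25L))
  # the uncorrelated stratum may be edgeless, which warns by design
  cmp <- suppressWarnings(
    compare_networks(list(hi = d_hi$traits, lo = d_lo$traits)))
  s <- cmp$summary
  expect_gt(s$edge_density[s$stratum == "hi"],
            s$edge_density[s$stratum == "lo"])
  hubs <- cmp$hubs$hi
  expect_true(all(diff(hubs$degree) <= 0))
  # identical data in two strata -> identical metrics
  cmp2 <- compare_networks(list(a = d_hi$traits, b = d_hi$traits))
  expect_equal(cmp2$summary$edge_density[1], cmp2$summary$edge_density[2])
  expect_equal(cmp2$summary$modularity[1], cmp2$summary$modularity[2])
})
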