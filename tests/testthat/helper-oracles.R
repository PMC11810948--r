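# Independent oracles used across the suite.

# Naive Blomberg's K: explicit matrix inverse, no shared code with the
# package implementation beyond the VCV definition.
naive_blomberg_k <- function(C, x) {
  n <- nrow(C)
  Ci <- solve(C)                      # explicit inverse on purpose
  one <- rep(1, n)
  a <- as.numeric((t(one) %*% Ci %*% x) / (t(one) %*% Ci %*% one))
  d <- x - a
  mse0 <- as.numeric(t(d) %*% d) / (n - 1)
  mse <- as.numeric(t(d) %*% Ci %*% d) / (n - 1)
  expected <- (sum(diag(C)) - n / as.numeric(t(one) %*% Ci %*% one)) / (n - 1)
  (mse0 / mse) / expected
}

# Hand-built VCV for the worked tree ((A:1,B:1):1,C:2)
hand_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")
hand_vcv <- function() {
  C <- matrix(c(2, 1, 0,
                1, 2, 0,
                0, 0, 2), 3, 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  C
}

# Random connected binary graph on n nodes (for modularity oracle checks)
random_connected_graph <- function(n, p = NULL) {
  if (is.null(p)) p <- runif(1, 0.2, 0.7)
  repeat {
    A <- matrix(0L, n, n)
    up <- which(upper.tri(A))
    A[up] <- rbinom(length(up), 1, p)
    A <- A + t(A)
    reach <- 1L
    repeat {
      nxt <- unique(c(reach, which(rowSums(A[, reach, drop = FALSE]) > 0)))
      if (length(nxt) == length(reach)) break
      reach <- nxt
    }
    if (length(reach) == n && sum(A) > 0) return(A)
  }
}

# F statistic for adding `extra` terms to `base`, from raw RSS comparison
brute_force_f <- function(rss_reduced, rss_full, df_num, df_den) {
  ((rss_reduced - rss_full) / df_num) / (rss_full / df_den)
}

# A small fully-null synthetic config (no species structure, no effects)
null_config <- function(seed, n_replicates = 3L) {
  synthetic_config(seed = seed, species_sd = 0, signal_lambda = 0,
                   n_replicates = n_replicates)
}

# Study-shaped config with the three trait categories as planted modules
module_config <- function(seed, rho = 0.85, n_replicates = 50L) {
  cat26 <- default_catalog()
  mods <- split(cat26$code, cat26$category)
  synthetic_config(seed = seed, species_sd = 0, signal_lambda = 0,
                   module_spec = mods, module_rho = rho,
                   n_replicates = n_replicates)
}

star_tree <- function(n) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}
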