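#' Blomberg's K for a trait on a phylogeny
#'
#' Computes the K statistic: the ratio of the observed
#' `MSE0/MSE` (mean squared error about the GLS ancestral mean, over the
#' phylogenetically corrected mean squared error) to its expectation
#' under Brownian motion on the given tree,
#' `[tr(C) - n / (1' C^-1 1)] / (n - 1)`. K = 1 is the Brownian-motion
#' expectation; K < 1 indicates weaker, K > 1 stronger phylogenetic
#' signal.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param x Named numeric vector of trait values covering every tip.
#' @return A list: `K`, `observed_ratio`, `expected_ratio`, `n`.
#' @export
blomberg_k <- function(tree, x) {
  validate_phylogeny(tree)
  tips <- tree$tip.label
  if (is.null(names(x)) || !all(tips %in% names(x)))
    stop("x must be named and cover every tip", call. = FALSE)
  x <- x[tips]
  if (anyNA(x)) stop("x contains missing values", call. = FALSE)
  if (stats::var(x) == 0)
    stop("zero trait variance", call. = FALSE)
  C <- phylo_vcv(tree)
  k_stat(C, x)
}

# Core K computation from a precomputed VCV; shared with the permutation
# null so C is factorized work done once per tree, not per shuffle.
k_prepare <- function(C) {
  n <- nrow(C)
  kappa <- kappa(C, exact = FALSE)
  if (!is.finite(kappa) || kappa > 1e12)
    stop("phylogenetic covariance is near-singular (condition number ",
         format(kappa, digits = 3), ")", call. = FALSE)
  Cinv1 <- solve(C, rep(1, n))
  s <- sum(Cinv1)                       # 1' C^-1 1
  expected <- (sum(diag(C)) - n / s) / (n - 1)
  list(C = C, Cinv1 = Cinv1, s = s, n = n, expected = expected)
}

k_from_prep <- function(prep, x) {
  a <- sum(prep$Cinv1 * x) / prep$s     # GLS ancestral mean
  d <- x - a
  mse0 <- sum(d * d) / (prep$n - 1)
  mse <- sum(d * solve(prep$C, d)) / (prep$n - 1)
  obs <- mse0 / mse
  list(K = obs / prep$expected, observed_ratio = obs,
       expected_ratio = prep$expected)
}

k_stat <- function(C, x) {
  prep <- k_prepare(C)
  r <- k_from_prep(prep, x)
  c(r, list(n = prep$n))
}

#' Permutation test of Blomberg's K
#'
#' Builds the null distribution of K by randomly shuffling trait values
#' across the tips of the tree (`n_perm` shuffles) and reports
#' `p = (1 + #\{K_null >= K_obs\}) / (n_perm + 1)`; a trait is considered
#' to carry significant phylogenetic signal when p < 0.05.
#'
#' @inheritParams blomberg_k
#' @param n_perm Number of tip shuffles (default 999, giving p-value
#'   resolution 1/1000).
#' @param seed Optional integer seed; fixing it makes K and p reproducible.
#' @return A list of class `k_result`: `K`, `p_value`, `n_permutations`,
#'   `observed_ratio`, `expected_ratio`, `seed`, `null_K` (the permuted
#'   K values).
#' @export
permutation_test_k <- function(tree, x, n_perm = 999L, seed = NULL) {
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  validate_phylogeny(tree)
  tips <- tree$tip.label
  if (is.null(names(x)) || !all(tips %in% names(x)))
    stop("x must be named and cover every tip", call. = FALSE)
  x <- x[tips]
  if (stats::var(x) == 0) stop("zero trait variance", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  prep <- k_prepare(phylo_vcv(tree))
  obs <- k_from_prep(prep, x)
  null_K <- vapply(seq_len(n_perm), function(i)
    k_from_prep(prep, sample(x))$K, numeric(1))
  p <- (1 + sum(null_K >= obs$K)) / (n_perm + 1)
  structure(list(K = obs$K, p_value = p, n_permutations = as.integer(n_perm),
                 observed_ratio = obs$observed_ratio,
                 expected_ratio = obs$expected_ratio,
                 seed = seed, null_K = null_K),
            class = "k_result")
}

#' Phylogenetic signal of every trait in a table
#'
#' Collapses replicates to per-species means (one tip per species) and
#' runs [permutation_test_k()] for each trait.
#'
#' @param table Trait table.
#' @param tree `phylo` whose tips are the table's species.
#' @param n_perm Number of tip shuffles per trait.
#' @param seed Integer seed (one stream for all traits; the run is
#'   reproducible as a whole).
#' @param collapse Function used to collapse a species' samples to one
#'   value (default `mean`).
#' @param catalog Trait catalog.
#' @return data.frame with columns `trait`, `K`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
phylo_signal_all <- function(table, tree, n_perm = 999L, seed = 42L,
                             collapse = mean, catalog = default_catalog()) {
  validate_phylogeny(tree)
  codes <- trait_codes(table, catalog)
  missing_sp <- setdiff(tree$tip.label, unique(table$species))
  if (length(missing_sp))
    stop("tree tip(s) absent from table: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(codes, function(code) {
    mu <- tapply(table[[code]], table$species, collapse, na.rm = TRUE)
    res <- permutation_test_k(tree, mu[tree$tip.label], n_perm = n_perm,
                              seed = NULL)
    data.frame(trait = code, K = res$K, p_value = res$p_value,
               n_permutations = res$n_permutations,
               seed = if (is.null(seed)) NA_integer_ else seed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
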