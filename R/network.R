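#' Spearman correlation and p-value matrices over traits
#'
#' Pairwise Spearman rank correlations (average ranks for ties) with
#' pairwise deletion of missing values. Two-sided p-values use the
#' t-approximation with df = n - 2; for fewer than 10 complete pairs the
#' exact null distribution of the rank statistic is used when ties
#' permit. Pairs with fewer than `min_pairs` complete observations are
#' flagged missing (`NA` in all three matrices) and can never become
#' edges.
#'
#' @param table Trait table (or numeric matrix with traits as columns).
#' @param catalog Trait catalog (ignored for matrix input).
#' @param min_pairs Minimum complete pairs required per trait pair.
#' @return A list of class `correlation_matrices`: `rho`, `p`, `n_pairs`
#'   (all traits x traits, symmetric; `rho` has unit diagonal).
#' @export
spearman_matrix <- function(table, catalog = default_catalog(),
                            min_pairs = 5L) {
  m <- if (is.matrix(table)) table else trait_matrix(table, catalog)
  k <- ncol(m)
  codes <- colnames(m)
  rho <- p <- np <- matrix(NA_real_, k, k, dimnames = list(codes, codes))
  diag(rho) <- 1; diag(np) <- colSums(is.finite(m))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ok <- is.finite(m[, i]) & is.finite(m[, j])
    n <- sum(ok)
    np[i, j] <- np[j, i] <- n
    if (n < min_pairs) next
    x <- m[ok, i]; y <- m[ok, j]
    r <- stats::cor(x, y, method = "spearman")
    if (is.na(r)) next
    pv <- spearman_p(x, y, r, n)
    rho[i, j] <- rho[j, i] <- r
    p[i, j] <- p[j, i] <- pv
  }
  structure(list(rho = rho, p = p, n_pairs = np),
            class = "correlation_matrices")
}

spearman_p <- function(x, y, r, n) {
  ties <- anyDuplicated(x) || anyDuplicated(y)
  if (n < 10L && !ties) {
    # exact null distribution of the rank statistic
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE))
    return(ct$p.value)
  }
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
}

#' Threshold correlation matrices into a binary trait network
#'
#' An (undirected, no self-loop) edge joins two traits iff
#' `|rho| > r_threshold` and `p < p_threshold`, both strict. Entries with
#' missing correlations never form edges.
#'
#' @param corr A `correlation_matrices` object from [spearman_matrix()].
#' @param r_threshold,p_threshold Thresholds in (0, 1).
#' @param catalog Trait catalog supplying node category labels.
#' @return A list of class `trait_network`: `adjacency` (binary symmetric
#'   matrix, zero diagonal), `nodes` (data.frame `code`, `category`),
#'   `rho`, `p`, `r_threshold`, `p_threshold`.
#' @export
binarize <- function(corr, r_threshold = 0.2, p_threshold = 0.05,
                     catalog = default_catalog()) {
  stopifnot(inherits(corr, "correlation_matrices"))
  if (r_threshold <= 0 || r_threshold >= 1 ||
      p_threshold <= 0 || p_threshold >= 1)
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  A <- (abs(corr$rho) > r_threshold) & (corr$p < p_threshold)
  A[is.na(A)] <- FALSE
  A <- A * 1L
  diag(A) <- 0L
  codes <- rownames(corr$rho)
  cats <- trait_categories(catalog)
  nodes <- data.frame(code = codes,
                      category = unname(cats[codes]),
                      stringsAsFactors = FALSE)
  structure(list(adjacency = A, nodes = nodes, rho = corr$rho, p = corr$p,
                 r_threshold = r_threshold, p_threshold = p_threshold),
            class = "trait_network")
}

#' Topology statistics of a trait network
#'
#' Degrees, edge density `E / (n (n - 1) / 2)`, a community partition by
#' deterministic greedy modularity maximization (agglomerative merges by
#' best Newman Q gain, ties broken toward the lowest-labelled pair,
#' followed by deterministic single-node reassignment until no move
#' improves Q), Newman's Q of that partition, the mean shortest-path
#' length over connected unordered pairs (flagged when the graph is
#' disconnected), and per-category relative importance.
#'
#' @param net A `trait_network`.
#' @param seed Unused by the deterministic algorithm; accepted and echoed
#'   for provenance.
#' @return A list of class `network_metrics`: `degree` (named), `n_edges`,
#'   `edge_density`, `modules` (named membership), `modularity`,
#'   `average_path_length`, `disconnected` (flag), `relative_importance`,
#'   `seed`. With no edges, modularity is 0 with singleton modules and
#'   the path length is `NA` (flagged).
#' @export
network_metrics <- function(net, seed = NULL) {
  stopifnot(inherits(net, "trait_network"))
  A <- net$adjacency
  n <- nrow(A)
  if (n < 1L) stop("network needs at least 1 node", call. = FALSE)
  deg <- rowSums(A)
  m <- sum(A) / 2
  density <- if (n >= 2L) m / (n * (n - 1) / 2) else NA_real_
  if (m == 0) {
    modules <- stats::setNames(seq_len(n), rownames(A))
    Q <- 0
    apl <- NA_real_
    disconnected <- n > 1L
  } else {
    comm <- greedy_modularity(A)
    modules <- comm$membership
    Q <- comm$modularity
    sp <- shortest_paths(A)
    finite <- is.finite(sp[upper.tri(sp)])
    disconnected <- !all(finite)
    apl <- if (any(finite)) mean(sp[upper.tri(sp)][finite]) else NA_real_
  }
  ri <- relative_importance_from_degree(deg, net$nodes)
  structure(list(degree = deg, n_edges = m, edge_density = density,
                 modules = modules, modularity = Q,
                 average_path_length = apl, disconnected = disconnected,
                 relative_importance = ri, seed = seed),
            class = "network_metrics")
}

# all-pairs shortest paths by BFS on a binary adjacency matrix
shortest_paths <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  nbr <- apply(A > 0, 1, which, simplify = FALSE)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(nbr[frontier], use.names = FALSE))
      nxt <- nxt[dist[nxt] == Inf]
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

#' Newman modularity of a given partition
#'
#' `Q = sum_c [e_c / m - (d_c / 2m)^2]` with `e_c` the within-community
#' edge count, `d_c` the community degree sum and `m` the total edge
#' count.
#'
#' @param A Binary symmetric adjacency matrix, zero diagonal.
#' @param membership Integer community labels, one per node.
#' @return Q (0 when the graph has no edges).
#' @export
modularity_q <- function(A, membership) {
  m <- sum(A) / 2
  if (m == 0) return(0)
  deg <- rowSums(A)
  f <- factor(membership)
  M <- rowsum(t(rowsum(A, f)), f)      # community x community edge counts
  dc <- as.numeric(rowsum(deg, f))
  sum(diag(M)) / (2 * m) - sum(dc^2) / (4 * m^2)
}

#' Deterministic greedy modularity maximization
#'
#' A fully deterministic community search built from three pieces:
#' (1) agglomerative (CNM-style) merging from singleton communities,
#' keeping every partition along the merge path (at each step the
#' connected community pair with the largest Q gain is merged, ties
#' broken toward the lowest-labelled pair); (2) recursive
#' leading-eigenvector bisections of the modularity matrix as additional
#' deterministic starting partitions; (3) each candidate partition is
#' refined to a strong local optimum by Kernighan-Lin node-move passes
#' (every node moved once per pass, best move even when negative, the
#' best partition along the pass kept) interleaved with exhaustive
#' optimal bipartitions of single communities and of pairwise community
#' unions (enumerated exactly for node sets of at most `max_exact`
#' nodes; larger pairs fall back to a plain merge test). The best refined
#' partition is returned. No randomness is involved, so repeated calls
#' agree exactly.
#'
#' @param A Binary symmetric adjacency matrix, zero diagonal.
#' @param max_exact Largest node set for which bipartitions are
#'   enumerated exhaustively during refinement.
#' @return A list: `membership` (named integer vector, labels densely
#'   renumbered in order of first appearance), `modularity`.
#' @export
greedy_modularity <- function(A, max_exact = 14L) {
  n <- nrow(A)
  m <- sum(A) / 2
  cur <- seq_len(n)
  starts <- list(cur)
  if (m > 0) {
    # CNM stage with a community-pair edge-count matrix; merge gain is
    # E[a, b] / m - d_a d_b / (2 m^2), no full Q recomputation needed
    E <- A / 1
    d <- rowSums(A)
    labels <- seq_len(n)                # community label per E row
    repeat {
      k <- length(labels)
      if (k == 1L) break
      gain <- E / m - outer(d, d) / (2 * m^2)
      gain[E == 0] <- -Inf
      diag(gain) <- -Inf
      bg <- max(gain)
      if (!is.finite(bg)) break         # no connected pairs left
      hit <- which(gain > bg - 1e-12, arr.ind = TRUE)
      hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
      # lowest-labelled pair among the tied maxima
      ord <- order(labels[hit[, 1]], labels[hit[, 2]])
      ii <- hit[ord[1L], 1L]; jj <- hit[ord[1L], 2L]
      cur[cur == labels[jj]] <- labels[ii]
      E[ii, ] <- E[ii, ] + E[jj, ]
      E[, ii] <- E[, ii] + E[, jj]
      E[ii, ii] <- E[ii, ii]            # self count accumulates cross edges
      d[ii] <- d[ii] + d[jj]
      E <- E[-jj, -jj, drop = FALSE]
      d <- d[-jj]
      labels <- labels[-jj]
      starts[[length(starts) + 1L]] <- cur
    }
  }
  starts <- c(starts, spectral_starts(A))
  best <- list(modularity = -Inf)
  for (p in starts) {
    r <- refine_membership(A, p, max_exact)
    if (r$modularity > best$modularity + 1e-12) best <- r
  }
  memb <- dense_labels(best$membership)
  names(memb) <- rownames(A)
  list(membership = memb, modularity = best$modularity)
}

# recursive leading-eigenvector bisection starting partitions
spectral_starts <- function(A) {
  n <- nrow(A)
  m <- sum(A) / 2
  if (m == 0) return(list())
  deg <- rowSums(A)
  memb <- rep(1L, n)
  out <- list()
  split_rec <- function(idx) {
    if (length(idx) < 2L) return(invisible())
    B <- A[idx, idx, drop = FALSE] - outer(deg[idx], deg[idx]) / (2 * m)
    diag(B) <- diag(B) -
      (rowSums(A[idx, idx, drop = FALSE]) - deg[idx] * sum(deg[idx]) / (2 * m))
    ev <- eigen((B + t(B)) / 2, symmetric = TRUE)
    if (ev$values[1] <= 1e-12) return(invisible())
    s <- ev$vectors[, 1] >= 0
    if (all(s) || !any(s)) return(invisible())
    new_label <- max(memb) + 1L
    memb[idx[!s]] <<- new_label
    out[[length(out) + 1L]] <<- memb
    split_rec(idx[s]); split_rec(idx[!s])
  }
  split_rec(seq_len(n))
  c(list(memb), out)
}

# optimal bipartition of the node set idx, all other communities fixed;
# subset DP: for each subset S of idx (element k held out of S) compute
# internal edges e_S and degree sum D_S by adding the lowest set bit, then
# score f(S) = (e_S + e_T)/m - (D_S^2 + D_T^2)/(4 m^2) with T = idx \ S
best_bipartition <- function(A, memb, idx, m) {
  k <- length(idx)
  base_q <- modularity_q(A, memb)
  if (k < 2L || m == 0) return(list(membership = memb, modularity = base_q))
  deg <- rowSums(A)
  sub <- A[idx, idx, drop = FALSE]
  e_all <- sum(sub) / 2
  D_all <- sum(deg[idx])
  # adjacency bitmask of each element over the first k-1 elements
  n_codes <- bitwShiftL(1L, k - 1L)
  pc <- integer(n_codes)                       # popcount table
  if (n_codes > 1L) for (i in 1L:(n_codes - 1L))
    pc[i + 1L] <- pc[bitwShiftR(i, 1L) + 1L] + bitwAnd(i, 1L)
  mask <- integer(k)
  for (v in seq_len(k))
    mask[v] <- sum(bitwShiftL(1L, which(sub[v, seq_len(k - 1L)] > 0) - 1L))
  e_S <- numeric(n_codes)                      # indexed by code + 1
  D_S <- numeric(n_codes)
  K_S <- numeric(n_codes)                      # edges from S into idx
  K_v <- rowSums(sub)
  for (code in seq_len(n_codes - 1L)) {
    low <- bitwAnd(code, -code)
    v <- 1L + pc[low]                          # log2(low) + 1
    rest <- code - low
    e_S[code + 1L] <- e_S[rest + 1L] + pc[bitwAnd(mask[v], rest) + 1L]
    D_S[code + 1L] <- D_S[rest + 1L] + deg[idx[v]]
    K_S[code + 1L] <- K_S[rest + 1L] + K_v[v]
  }
  codes <- seq_len(n_codes - 1L)
  e_T <- e_all + e_S[codes + 1L] - K_S[codes + 1L]
  D_T <- D_all - D_S[codes + 1L]
  f <- (e_S[codes + 1L] + e_T) / m -
    (D_S[codes + 1L]^2 + D_T^2) / (4 * m^2)
  f0 <- e_all / m - D_all^2 / (4 * m^2)        # unsplit value
  best_code <- codes[which.max(f)]
  if (max(f) <= f0 + 1e-12)
    return(list(membership = memb, modularity = base_q))
  bits <- as.integer(intToBits(best_code))[seq_len(k - 1L)]
  trial <- memb
  trial[idx] <- memb[idx[k]]                   # merge, then carve S out
  trial[idx[which(bits == 1L)]] <- max(memb) + 1L
  list(membership = trial, modularity = modularity_q(A, trial))
}

# one Kernighan-Lin pass: each node moved at most once, the globally best
# move applied even when it lowers Q, best partition along the pass kept;
# node-move gains are computed incrementally
kl_pass <- function(A, memb, q, m) {
  n <- nrow(A)
  deg <- rowSums(A)
  locked <- rep(FALSE, n)
  cur <- memb
  best_q <- q; best <- memb; cur_q <- q
  for (step in seq_len(n)) {
    d_c <- tapply(deg, cur, sum)
    bq_gain <- -Inf; bv <- NA_integer_; bc <- NA_integer_
    free_label <- max(cur) + 1L
    for (v in which(!locked)) {
      a <- cur[v]
      k_vc <- tapply(A[v, ], cur, sum)         # edges from v per community
      d_a_minus <- d_c[[as.character(a)]] - deg[v]
      cands <- c(setdiff(as.integer(names(k_vc)), a), free_label)
      for (cc in cands) {
        key <- as.character(cc)
        k_vb <- if (key %in% names(k_vc)) k_vc[[key]] else 0
        d_b <- if (key %in% names(d_c)) d_c[[key]] else 0
        gain <- (k_vb - k_vc[[as.character(a)]]) / m -
          deg[v] * (d_b - d_a_minus) / (2 * m^2)
        if (gain > bq_gain + 1e-12) { bq_gain <- gain; bv <- v; bc <- cc }
      }
    }
    if (is.na(bv)) break
    cur[bv] <- bc; locked[bv] <- TRUE
    cur_q <- cur_q + bq_gain
    if (cur_q > best_q + 1e-12) { best_q <- cur_q; best <- cur }
  }
  list(membership = best, modularity = modularity_q(A, best))
}

refine_membership <- function(A, memb, max_exact = 14L) {
  m <- sum(A) / 2
  q <- modularity_q(A, memb)
  if (m == 0) return(list(membership = memb, modularity = q))
  deg <- rowSums(A)
  repeat {
    improved <- FALSE
    r <- kl_pass(A, memb, q, m)
    if (r$modularity > q + 1e-12) {
      memb <- r$membership; q <- r$modularity; improved <- TRUE
    }
    for (c in sort(unique(memb))) {
      idx <- which(memb == c)
      if (length(idx) >= 2L && length(idx) <= max_exact) {
        r <- best_bipartition(A, memb, idx, m)
        if (r$modularity > q + 1e-12) {
          memb <- r$membership; q <- r$modularity; improved <- TRUE
        }
      }
    }
    comms <- sort(unique(memb))
    if (length(comms) > 1L) for (ii in seq_along(comms)) {
      for (jj in seq_along(comms)) {
        if (jj <= ii) next
        a <- comms[ii]; b <- comms[jj]
        if (!any(memb == a) || !any(memb == b)) next  # relabelled earlier
        idx <- which(memb %in% c(a, b))
        if (length(idx) > max_exact) {
          # plain merge test via the closed-form gain
          e_ab <- sum(A[memb == a, memb == b, drop = FALSE])
          gain <- e_ab / m -
            sum(deg[memb == a]) * sum(deg[memb == b]) / (2 * m^2)
          if (gain > 1e-12) {
            memb[memb == b] <- a
            q <- q + gain; improved <- TRUE
          }
          next
        }
        merged <- memb; merged[idx] <- a
        r <- best_bipartition(A, merged, idx, m)
        if (r$modularity > q + 1e-12) {
          memb <- r$membership; q <- r$modularity; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(membership = memb, modularity = modularity_q(A, memb))
}

dense_labels <- function(memb) {
  as.integer(factor(memb, levels = unique(memb)))
}

#' Exhaustive maximum-modularity partition (small graphs)
#'
#' Enumerates every set partition of the nodes (restricted-growth
#' strings) and returns the maximum Newman Q. Intended as an independent
#' oracle for graphs with at most ~10 nodes.
#'
#' @param A Binary symmetric adjacency matrix, zero diagonal.
#' @return A list: `membership` (integer labels), `modularity`.
#' @export
exhaustive_modularity <- function(A) {
  n <- nrow(A)
  if (n > 12L) stop("exhaustive search limited to n <= 12", call. = FALSE)
  best_q <- -Inf; best <- NULL
  memb <- integer(n)
  recurse <- function(i, k, memb) {
    if (i > n) {
      q <- modularity_q(A, memb)
      if (q > best_q) { best_q <<- q; best <<- memb }
      return(invisible())
    }
    for (c in seq_len(k + 1L)) {
      memb[i] <- c
      recurse(i + 1L, max(k, c), memb)
    }
  }
  recurse(1L, 0L, memb)
  names(best) <- rownames(A)
  list(membership = best, modularity = best_q)
}

relative_importance_from_degree <- function(deg, nodes) {
  cats <- sort(unique(nodes$category))
  total <- sum(deg)
  ri <- vapply(cats, function(cat) {
    idx <- nodes$category == cat
    if (total == 0) 0 else mean(deg[idx]) / total
  }, numeric(1))
  if (total == 0)
    warning("all degrees are zero; relative importance is 0 for every category")
  stats::setNames(ri, cats)
}

#' Relative importance of trait categories
#'
#' `RI_cat = (mean degree of traits in the category) / (sum of all trait
#' degrees)`. Invariant to rescaling all degrees by a constant.
#'
#' @param metrics A `network_metrics` object.
#' @param catalog Trait catalog labelling each trait with its category.
#' @return Named numeric vector, one fraction per category.
#' @export
relative_importance <- function(metrics, catalog = default_catalog()) {
  stopifnot(inherits(metrics, "network_metrics"))
  deg <- metrics$degree
  cats <- trait_categories(catalog)[names(deg)]
  relative_importance_from_degree(
    deg, data.frame(code = names(deg), category = unname(cats)))
}

#' Build a trait network from a trait table
#'
#' Convenience wrapper: [spearman_matrix()] then [binarize()].
#'
#' @inheritParams spearman_matrix
#' @inheritParams binarize
#' @export
build_network <- function(table, r_threshold = 0.2, p_threshold = 0.05,
                          catalog = default_catalog(), min_pairs = 5L) {
  binarize(spearman_matrix(table, catalog, min_pairs),
           r_threshold, p_threshold, catalog)
}

#' Per-stratum trait networks with side-by-side metrics
#'
#' Builds one thresholded network per stratum (e.g. plant type, or
#' low/middle/high elevation band) from that stratum's samples and
#' reports the topology metrics side by side, plus a hub report (traits
#' by decreasing degree, ties label-ordered).
#'
#' @param tables Named list of trait tables, one per stratum (use
#'   [split_strata()] to build it).
#' @inheritParams build_network
#' @param min_samples Strata with fewer samples are skipped with a
#'   warning.
#' @param seed Echoed into each stratum's metrics.
#' @return A list of class `network_comparison`: `networks` (per-stratum
#'   `trait_network`), `metrics` (per-stratum `network_metrics`),
#'   `summary` (data.frame: stratum, n_samples, n_edges, edge_density,
#'   modularity, n_modules, average_path_length), `hubs` (per-stratum
#'   data.frame of traits sorted by degree).
#' @export
compare_networks <- function(tables, r_threshold = 0.2, p_threshold = 0.05,
                             catalog = default_catalog(), min_pairs = 5L,
                             min_samples = 6L, seed = NULL) {
  if (length(tables) < 2L) stop("need at least 2 strata", call. = FALSE)
  if (is.null(names(tables))) stop("strata must be named", call. = FALSE)
  networks <- list(); metrics <- list(); hubs <- list(); rows <- list()
  for (s in names(tables)) {
    tab <- tables[[s]]
    if (nrow(tab) < min_samples) {
      warning("stratum '", s, "' has too few samples; skipped")
      next
    }
    net <- build_network(tab, r_threshold, p_threshold, catalog, min_pairs)
    met <- network_metrics(net, seed = seed)
    networks[[s]] <- net
    metrics[[s]] <- met
    deg <- met$degree
    ord <- order(-deg, names(deg))
    hubs[[s]] <- data.frame(stratum = s, trait = names(deg)[ord],
                            degree = unname(deg)[ord],
                            stringsAsFactors = FALSE)
    rows[[s]] <- data.frame(
      stratum = s, n_samples = nrow(tab), n_edges = met$n_edges,
      edge_density = met$edge_density, modularity = met$modularity,
      n_modules = length(unique(met$modules)),
      average_path_length = met$average_path_length,
      disconnected = met$disconnected, stringsAsFactors = FALSE)
  }
  structure(list(networks = networks, metrics = metrics,
                 summary = do.call(rbind, c(rows, make.row.names = FALSE)),
                 hubs = hubs),
            class = "network_comparison")
}

#' Split a trait table into strata
#'
#' @param table Trait table.
#' @param by `"type"` (plant type) or `"elevation"` (elevation band).
#' @return Named list of trait tables.
#' @export
split_strata <- function(table, by = c("type", "elevation")) {
  by <- match.arg(by)
  f <- if (by == "type") table$plant_type else
    paste0("elev_", table$elevation_m)
  split(table, f)
}
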