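#' Shapiro-Wilk normality gate for a two-group comparison
#'
#' Returns `TRUE` only when the Shapiro-Wilk test fails to reject
#' normality (p > `alpha`) in both groups; the gate decides between the
#' paired t-test and the Mann-Whitney test in [compare_trait()]. Groups
#' with fewer than 3 values (where the test is undefined) gate to `FALSE`
#' with a warning, as do degenerate constant groups.
#'
#' @param x,y Numeric vectors, one per group.
#' @param alpha Significance level of the Shapiro-Wilk tests.
#' @return Logical scalar.
#' @export
normality_gate <- function(x, y, alpha = 0.05) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3L || length(y) < 3L) {
    warning("normality test undefined for n < 3; gate is FALSE")
    return(FALSE)
  }
  sw <- function(v) {
    if (length(v) > 5000L) v <- v[seq_len(5000L)]
    tryCatch(stats::shapiro.test(v)$p.value, error = function(e) 0)
  }
  sw(x) > alpha && sw(y) > alpha
}

pair_means <- function(table, trait) {
  # mean per (elevation, replicate) within each plant type
  key <- interaction(table$elevation_m, table$replicate, drop = TRUE)
  eph <- tapply(table[[trait]][table$plant_type == "ephemeral"],
                key[table$plant_type == "ephemeral"], mean, na.rm = TRUE)
  non <- tapply(table[[trait]][table$plant_type == "non_ephemeral"],
                key[table$plant_type == "non_ephemeral"], mean, na.rm = TRUE)
  shared <- intersect(names(eph), names(non))
  cbind(eph = as.numeric(eph[shared]), non = as.numeric(non[shared]))
}

#' Compare one trait between ephemeral and non-ephemeral plants
#'
#' Applies the normality gate ([normality_gate()]) to the two groups; when
#' it passes, a paired t-test on elevation x replicate matched group means
#' (the default pairing), otherwise a two-sided Mann-Whitney test on all
#' values. The Mann-Whitney test is exact for combined n <= 20 without
#' ties, and uses the normal approximation with tie correction otherwise.
#'
#' @param trait A trait code present in `table`.
#' @param table A trait table.
#' @param pairing `"elevation_replicate"` (default: pair group means
#'   within the same elevation band and replicate index) or `"unpaired"`
#'   (Welch t-test when the gate passes).
#' @param alpha Level of the normality gate.
#' @return A one-row data.frame: `trait`, `chosen_test`, `statistic`,
#'   `p_value`, group means and medians, and `direction` (which group is
#'   higher on the mean).
#' @export
compare_trait <- function(trait, table,
                          pairing = c("elevation_replicate", "unpaired"),
                          alpha = 0.05) {
  pairing <- match.arg(pairing)
  if (!trait %in% names(table))
    stop("trait '", trait, "' not found in table", call. = FALSE)
  x <- table[[trait]][table$plant_type == "ephemeral"]
  y <- table[[trait]][table$plant_type == "non_ephemeral"]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y))
    stop("both plant types must be present", call. = FALSE)

  gate <- withCallingHandlers(normality_gate(x, y, alpha),
                              warning = function(w) invokeRestart("muffleWarning"))
  if (gate) {
    if (pairing == "elevation_replicate") {
      pm <- pair_means(table[is.finite(table[[trait]]), , drop = FALSE], trait)
      if (nrow(pm) >= 2L) {
        ht <- stats::t.test(pm[, "eph"], pm[, "non"], paired = TRUE)
        chosen <- "paired_t"
      } else {
        warning("no matched pairs; falling back to unpaired t-test")
        ht <- stats::t.test(x, y)
        chosen <- "unpaired_t"
      }
    } else {
      ht <- stats::t.test(x, y)
      chosen <- "unpaired_t"
    }
  } else {
    exact <- (length(x) + length(y) <= 20L) &&
      !anyDuplicated(c(x, y))
    ht <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    chosen <- "mann_whitney"
  }
  data.frame(
    trait = trait, chosen_test = chosen,
    statistic = unname(ht$statistic), p_value = ht$p.value,
    mean_ephemeral = mean(x), mean_non_ephemeral = mean(y),
    median_ephemeral = stats::median(x),
    median_non_ephemeral = stats::median(y),
    direction = if (mean(x) >= mean(y)) "ephemeral" else "non_ephemeral",
    stringsAsFactors = FALSE)
}

#' Compare every trait between the two plant types
#'
#' @inheritParams compare_trait
#' @param catalog Trait catalog.
#' @return A data.frame, one row per trait, as in [compare_trait()], plus
#'   a Benjamini-Hochberg adjusted p-value column `p_adjust_BH` (reported
#'   for reference; the per-trait decisions use raw p-values).
#' @export
compare_all_traits <- function(table, catalog = default_catalog(),
                               pairing = "elevation_replicate",
                               alpha = 0.05) {
  codes <- trait_codes(table, catalog)
  out <- do.call(rbind, lapply(codes, compare_trait, table = table,
                               pairing = pairing, alpha = alpha))
  out$p_adjust_BH <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Standardize the trait matrix
#'
#' Centers each trait to mean 0 and scales to sample standard deviation 1
#' (n - 1 denominator). Zero-variance traits are dropped with a warning.
#' `NA` values are ignored for the statistics and preserved in place.
#'
#' @param table A trait table (or a plain numeric matrix).
#' @param catalog Trait catalog (ignored for matrix input).
#' @return Numeric matrix, samples x retained traits.
#' @export
standardize_traits <- function(table, catalog = default_catalog()) {
  m <- if (is.matrix(table)) table else trait_matrix(table, catalog)
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  drop <- !is.finite(sds) | sds == 0
  if (any(drop)) {
    warning("zero-variance trait(s) excluded: ",
            paste(colnames(m)[drop], collapse = ", "))
    m <- m[, !drop, drop = FALSE]
  }
  scale(m)[, , drop = FALSE]
}

#' PCA of the standardized trait matrix
#'
#' Eigendecomposition of the trait correlation matrix via singular value
#' decomposition of the standardized data. Components are ordered by
#' decreasing variance explained; each component's sign is fixed so its
#' largest-magnitude loading is positive.
#'
#' @param z A standardized matrix from [standardize_traits()] (rows with
#'   missing values are dropped listwise).
#' @return A list of class `trait_pca`: `loadings` (trait x component,
#'   orthonormal columns), `scores` (sample x component) and
#'   `variance_explained` (fractions summing to 1).
#' @export
trait_pca <- function(z) {
  z <- z[stats::complete.cases(z), , drop = FALSE]
  if (nrow(z) < 2L || ncol(z) < 2L)
    stop("PCA needs at least 2 rows and 2 columns", call. = FALSE)
  z <- scale(z)  # restandardize after row drops
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = loadings, scores = scores,
                 variance_explained = ve), class = "trait_pca")
}
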