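#' Simulate a Brownian-motion trait on a phylogeny
#'
#' Draws one realization of a Brownian-motion trait: independent normal
#' increments with variance `sigma2 * branch length` accumulated from the
#' root, so tip values have covariance `sigma2 * C` with `C` the
#' phylogenetic VCV ([phylo_vcv()]).
#'
#' @param tree A `phylo` object with branch lengths.
#' @param sigma2 Brownian rate (variance per unit branch length), `>= 0`.
#' @param root_value Trait value at the root.
#' @param seed Optional integer seed; when given the draw is reproducible.
#' @return Named numeric vector of tip values, in tip-label order.
#' @export
simulate_bm <- function(tree, sigma2 = 1, root_value = 0, seed = NULL) {
  validate_phylogeny(tree)
  if (!is.numeric(sigma2) || length(sigma2) != 1L || !is.finite(sigma2) ||
      sigma2 < 0)
    stop("sigma2 must be a single finite number >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  val <- rep(NA_real_, n_node)
  root <- n_tip + 1L
  val[root] <- root_value
  # preorder: parents are assigned before children
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
  inc <- if (sigma2 > 0) stats::rnorm(nrow(edges), 0, sqrt(sigma2 * lens))
         else numeric(nrow(edges))
  for (k in seq_len(nrow(edges)))
    val[edges[k, 2L]] <- val[edges[k, 1L]] + inc[k]
  stats::setNames(val[seq_len(n_tip)], tree$tip.label)
}

#' Default species set of the study design
#'
#' Four spring ephemeral and four spring non-ephemeral understory herbs.
#' @return data.frame with columns `species`, `plant_type`.
#' @export
default_species <- function() {
  data.frame(
    species = c("Anemone_raddeana", "Erythronium_japonicum",
                "Adonis_amurensis", "Hylomecon_japonicum",
                "Angelica_dahurica", "Aegopodium_alpestre",
                "Cardamine_leucantha", "Pimpinella_brachycarpa"),
    plant_type = rep(c("ephemeral", "non_ephemeral"), each = 4L),
    stringsAsFactors = FALSE)
}

#' Default per-band environment table
#'
#' Site-level soil and climate summaries for the three elevation bands
#' (means per band; used as the synthetic generator's environment output).
#' @return data.frame, one row per elevation band.
#' @export
default_environment <- function() {
  data.frame(
    elevation_m = c(600, 800, 1000),
    soil_pH  = c(6.187, 5.770, 5.617),
    soil_C   = c(6.840, 8.877, 11.243),
    soil_P   = c(0.100, 0.080, 0.083),
    soil_N   = c(1.073, 0.803, 0.953),
    soil_EC  = c(176.000, 132.000, 129.333),
    MAP      = c(69.230, 71.593, 72.600),
    MASR     = c(13715.830, 13559.750, 13559.113),
    MAT      = c(3.820, 2.980, 2.507))
}

#' Configuration for the synthetic trait-data generator
#'
#' Bundles every knob of [generate_dataset()] with the study-design
#' defaults: 8 species (4 ephemeral, 4 non-ephemeral) at elevation bands
#' 600/800/1000 m with 3 replicate samples per species x band.
#'
#' The species-level value of each trait is
#' `species_sd * (sqrt(lambda) * z_BM + sqrt(1 - lambda) * z_iid)`,
#' a blend of a standardized Brownian-motion draw on the tree and
#' standardized white noise; `signal_lambda = 1` gives a pure BM trait,
#' `species_sd = 0` removes between-species structure entirely. Type
#' offsets (added to ephemerals), elevation slopes and interaction slopes
#' (per km, interaction applied to ephemerals) shift the species x band
#' mean. Replicate-level residuals are `noise_sd`-scaled; traits listed in
#' one `module_spec` module share a latent factor with loading `rho`,
#' giving within-module pairwise correlation `rho^2`.
#'
#' @param n_species,n_ephemeral Species counts (defaults 8 and 4); ignored
#'   when `species` is supplied.
#' @param species Optional data.frame (`species`, `plant_type`) overriding
#'   the default species set.
#' @param elevations_m Elevation bands in meters.
#' @param n_replicates Replicate samples per species x band.
#' @param tree Optional `phylo`; when `NULL` a random coalescent tree over
#'   the species (scaled to unit depth) is simulated from `seed`.
#' @param signal_lambda Either a single value in `[0, 1]` or a named
#'   vector per trait code: weight of the phylogenetic (BM) component.
#' @param species_sd Standard deviation of the species-level component.
#' @param module_spec Named list of character vectors partitioning a
#'   subset of trait codes into latent modules, e.g.
#'   `list(m1 = c("LC", "LN"), m2 = c("RS", "RSS"))`.
#' @param module_rho Either a single loading in `[0, 1)` or a named vector
#'   (one entry per module in `module_spec`).
#' @param type_offsets Named vector, trait code -> mean shift added to
#'   ephemeral samples (standardized units).
#' @param elevation_slopes Named vector, trait code -> slope per km.
#' @param interaction_slopes Named vector, trait code -> additional slope
#'   per km applied to ephemerals.
#' @param noise_sd Replicate-level residual standard deviation, `> 0`.
#' @param seed Integer seed; a fixed seed gives a byte-identical dataset.
#' @param catalog Trait catalog.
#' @return An object of class `synthetic_config` (a list).
#' @export
synthetic_config <- function(n_species = 8L, n_ephemeral = 4L,
                             species = NULL,
                             elevations_m = c(600, 800, 1000),
                             n_replicates = 3L,
                             tree = NULL,
                             signal_lambda = 0,
                             species_sd = 1,
                             module_spec = list(),
                             module_rho = 0,
                             type_offsets = numeric(0),
                             elevation_slopes = numeric(0),
                             interaction_slopes = numeric(0),
                             noise_sd = 1,
                             seed = 1L,
                             catalog = default_catalog()) {
  if (is.null(species)) {
    if (n_species == 8L && n_ephemeral == 4L) {
      species <- default_species()
    } else {
      if (n_ephemeral > n_species)
        stop("n_ephemeral cannot exceed n_species", call. = FALSE)
      species <- data.frame(
        species = sprintf("sp%02d", seq_len(n_species)),
        plant_type = rep(c("ephemeral", "non_ephemeral"),
                         c(n_ephemeral, n_species - n_ephemeral)),
        stringsAsFactors = FALSE)
    }
  }
  codes <- catalog$code
  expand <- function(x, what, lo, hi, strict_hi = FALSE) {
    if (length(x) == 1L && is.null(names(x)))
      x <- stats::setNames(rep(as.numeric(x), length(codes)), codes)
    bad <- setdiff(names(x), codes)
    if (length(bad))
      stop("unknown trait code(s) in ", what, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (any(x < lo) || any(if (strict_hi) x >= hi else x > hi))
      stop(what, " out of range", call. = FALSE)
    x
  }
  signal_lambda <- expand(signal_lambda, "signal_lambda", 0, 1)
  if (length(signal_lambda) < length(codes)) {
    # partial named spec: unnamed traits carry no phylogenetic component
    full <- stats::setNames(rep(0, length(codes)), codes)
    full[names(signal_lambda)] <- signal_lambda
    signal_lambda <- full
  }
  if (length(module_spec)) {
    all_mod <- unlist(module_spec, use.names = FALSE)
    bad <- setdiff(all_mod, codes)
    if (length(bad))
      stop("module_spec config error: unknown trait code(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (anyDuplicated(all_mod))
      stop("module_spec config error: overlapping modules (",
           paste(unique(all_mod[duplicated(all_mod)]), collapse = ", "),
           ")", call. = FALSE)
    if (is.null(names(module_spec)))
      names(module_spec) <- sprintf("module%d", seq_along(module_spec))
    if (length(module_rho) == 1L && is.null(names(module_rho)))
      module_rho <- stats::setNames(rep(as.numeric(module_rho),
                                        length(module_spec)),
                                    names(module_spec))
    if (any(module_rho < 0) || any(module_rho >= 1))
      stop("module loadings must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("noise_sd must be > 0", call. = FALSE)
  structure(list(
    species = species, elevations_m = elevations_m,
    n_replicates = as.integer(n_replicates), tree = tree,
    signal_lambda = signal_lambda, species_sd = species_sd,
    module_spec = module_spec, module_rho = module_rho,
    type_offsets = expand(type_offsets, "type_offsets", -Inf, Inf),
    elevation_slopes = expand(elevation_slopes, "elevation_slopes",
                              -Inf, Inf),
    interaction_slopes = expand(interaction_slopes, "interaction_slopes",
                                -Inf, Inf),
    noise_sd = noise_sd, seed = as.integer(seed), catalog = catalog),
    class = "synthetic_config")
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Generate a synthetic trait dataset with known ground truth
#'
#' Realizes the data-generating model described in [synthetic_config()]
#' and returns the trait table together with the tree, the per-band
#' environment table, and a ground-truth record echoing every planted
#' parameter. Identical configs (same seed) give identical datasets.
#'
#' @param config A `synthetic_config`.
#' @return A list with elements `traits` (trait table), `tree` (`phylo`),
#'   `environment` (data.frame) and `truth` (list of planted parameters).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  sp <- config$species
  n_sp <- nrow(sp)
  codes <- config$catalog$code
  tree <- config$tree
  if (is.null(tree)) {
    tree <- ape::rcoal(n_sp, tip.label = sp$species)
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / depth
  } else {
    validate_phylogeny(tree)
    if (!setequal(tree$tip.label, sp$species))
      stop("tree tips must match the species set", call. = FALSE)
  }

  elev_km <- config$elevations_m / 1000
  design <- expand.grid(replicate = seq_len(config$n_replicates),
                        elevation_m = config$elevations_m,
                        species = sp$species,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("species", "elevation_m", "replicate")]
  design$plant_type <- sp$plant_type[match(design$species, sp$species)]
  n <- nrow(design)
  is_eph <- design$plant_type == "ephemeral"
  ekm <- design$elevation_m / 1000

  # species-level components, one independent draw per trait
  lam <- config$signal_lambda
  sp_base <- matrix(0, n_sp, length(codes),
                    dimnames = list(sp$species, codes))
  if (config$species_sd > 0) {
    for (j in seq_along(codes)) {
      l <- lam[[codes[j]]]
      bm <- if (l > 0) zscore(simulate_bm(tree, sigma2 = 1)) else
        numeric(n_sp)
      wn <- if (l < 1) zscore(stats::rnorm(n_sp)) else numeric(n_sp)
      if (l == 0) bm <- rep(0, n_sp)
      if (l == 1) wn <- rep(0, n_sp)
      sp_base[, j] <- config$species_sd *
        (sqrt(l) * bm[seq_len(n_sp)] + sqrt(1 - l) * wn)
    }
  }

  # replicate-level residuals: shared latent factor within each module
  resid <- matrix(stats::rnorm(n * length(codes)), n, length(codes),
                  dimnames = list(NULL, codes))
  for (m in names(config$module_spec)) {
    members <- config$module_spec[[m]]
    rho <- config$module_rho[[m]]
    if (rho > 0) {
      f <- stats::rnorm(n)
      for (code in members)
        resid[, code] <- rho * f + sqrt(1 - rho^2) * resid[, code]
    }
  }

  values <- matrix(0, n, length(codes), dimnames = list(NULL, codes))
  off <- config$type_offsets; slp <- config$elevation_slopes
  isl <- config$interaction_slopes
  for (j in seq_along(codes)) {
    code <- codes[j]
    mu <- sp_base[match(design$species, sp$species), j]
    if (code %in% names(off)) mu <- mu + off[[code]] * is_eph
    if (code %in% names(slp)) mu <- mu + slp[[code]] * ekm
    if (code %in% names(isl)) mu <- mu + isl[[code]] * ekm * is_eph
    values[, j] <- mu + config$noise_sd * resid[, j]
  }

  traits <- cbind(design[, c("species", "plant_type", "elevation_m",
                             "replicate")],
                  as.data.frame(values))
  traits <- validate_trait_table(traits, config$catalog)

  truth <- list(
    species = sp, elevations_m = config$elevations_m,
    n_replicates = config$n_replicates,
    signal_lambda = config$signal_lambda, species_sd = config$species_sd,
    module_spec = config$module_spec, module_rho = config$module_rho,
    type_offsets = config$type_offsets,
    elevation_slopes = config$elevation_slopes,
    interaction_slopes = config$interaction_slopes,
    noise_sd = config$noise_sd, seed = config$seed,
    species_base = sp_base)
  list(traits = traits, tree = tree, environment = default_environment(),
       truth = truth)
}

#' Generate a synthetic quadrat survey
#'
#' Individuals in each quadrat are dropped multinomially over species with
#' the given abundance weights; cover is proportional to counts with
#' multiplicative lognormal noise.
#'
#' @param n_plots Number of plots.
#' @param n_quadrats Quadrats per plot (must be `>= 1`).
#' @param abundance_weights Named nonnegative vector, species -> relative
#'   abundance (not all zero).
#' @param n_individuals Expected individuals per quadrat.
#' @param cover_per_individual Mean cover fraction contributed by one
#'   individual.
#' @param seed Optional integer seed.
#' @return A survey data.frame with columns `plot`, `quadrat`, `species`,
#'   `count`, `cover` (species with zero count in a quadrat are omitted).
#' @export
generate_survey <- function(n_plots = 3L, n_quadrats = 5L,
                            abundance_weights,
                            n_individuals = 30L,
                            cover_per_individual = 0.02,
                            seed = NULL) {
  if (n_quadrats < 1L) stop("n_quadrats must be >= 1", call. = FALSE)
  if (n_plots < 1L) stop("n_plots must be >= 1", call. = FALSE)
  if (is.null(names(abundance_weights)) || any(abundance_weights < 0) ||
      sum(abundance_weights) <= 0)
    stop("abundance_weights must be named, nonnegative, not all zero",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sp <- names(abundance_weights)
  p <- abundance_weights / sum(abundance_weights)
  rows <- list()
  for (pl in seq_len(n_plots)) for (q in seq_len(n_quadrats)) {
    counts <- as.integer(stats::rmultinom(1, size = n_individuals, prob = p))
    keep <- counts > 0L
    if (!any(keep)) next
    cover <- pmin(1, counts[keep] * cover_per_individual *
                       stats::rlnorm(sum(keep), 0, 0.25))
    rows[[length(rows) + 1L]] <- data.frame(
      plot = sprintf("P%02d", pl), quadrat = sprintf("Q%02d", q),
      species = sp[keep], count = counts[keep], cover = cover,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
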