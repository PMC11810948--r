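#' Linear model of one trait on plant type, elevation and interaction
#'
#' Ordinary least squares of `trait ~ group + elevation + group:elevation`
#' with elevation continuous (meters, centered at its mean for numerical
#' stability). F-tests use sequential (type-I) sums of squares in the
#' stated order by default; `ss = 2` gives type-II tests (each main
#' effect adjusted for the other, the interaction adjusted for both) via
#' nested-model comparisons.
#'
#' @param trait Trait code.
#' @param table Trait table; rows with a missing trait value are dropped
#'   (listwise).
#' @param species_mode `"type"` (default; group = ephemeral vs
#'   non-ephemeral) or `"species"` (group = individual species).
#' @param ss `1` (sequential) or `2` (type-II) sums of squares.
#' @return A list of class `trait_model_fit`: `anova` (data.frame with
#'   `term`, `df`, `sum_sq`, `F`, `p`), `coefficients` (estimate, SE, t,
#'   p), `r_squared`, `residual_df`, and the fitted `lm` object as `fit`.
#' @export
fit_trait_model <- function(trait, table, species_mode = c("type", "species"),
                            ss = 1) {
  species_mode <- match.arg(species_mode)
  d <- model_frame(trait, table, species_mode)
  if (nlevels(d$group) < 2L)
    stop("singular design: factor 'group' has a single level", call. = FALSE)
  if (length(unique(d$elev_c)) < 2L)
    stop("singular design: factor 'elevation' is constant", call. = FALSE)
  if (nrow(d) <= 4L) stop("need n > 4 samples", call. = FALSE)

  fit <- stats::lm(y ~ group + elev_c + group:elev_c, data = d)
  if (ss == 1) {
    a <- stats::anova(fit)
    an <- data.frame(term = c("group", "elevation", "group:elevation"),
                     df = a$Df[1:3], sum_sq = a$`Sum Sq`[1:3],
                     F = a$`F value`[1:3], p = a$`Pr(>F)`[1:3],
                     stringsAsFactors = FALSE)
    an <- rbind(an, data.frame(term = "residual", df = a$Df[4],
                               sum_sq = a$`Sum Sq`[4], F = NA, p = NA))
  } else if (ss == 2) {
    rss <- function(f) sum(stats::resid(f)^2)
    full2 <- stats::lm(y ~ group + elev_c, data = d)
    dfr2 <- stats::df.residual(full2)
    cmp <- function(reduced, full, df_num, dfr) {
      Fv <- ((rss(reduced) - rss(full)) / df_num) / (rss(full) / dfr)
      c(F = Fv, p = stats::pf(Fv, df_num, dfr, lower.tail = FALSE),
        ss = rss(reduced) - rss(full), df = df_num)
    }
    k <- nlevels(d$group) - 1L
    g <- cmp(stats::lm(y ~ elev_c, data = d), full2, k, dfr2)
    e <- cmp(stats::lm(y ~ group, data = d), full2, 1L, dfr2)
    i <- cmp(full2, fit, k, stats::df.residual(fit))
    an <- data.frame(term = c("group", "elevation", "group:elevation",
                              "residual"),
                     df = c(g["df"], e["df"], i["df"],
                            stats::df.residual(fit)),
                     sum_sq = c(g["ss"], e["ss"], i["ss"], rss(fit)),
                     F = c(g["F"], e["F"], i["F"], NA),
                     p = c(g["p"], e["p"], i["p"], NA),
                     stringsAsFactors = FALSE)
  } else stop("ss must be 1 or 2", call. = FALSE)

  cf <- summary(fit)$coefficients
  structure(list(
    trait = trait, species_mode = species_mode, ss = ss, anova = an,
    coefficients = data.frame(term = rownames(cf), estimate = cf[, 1],
                              se = cf[, 2], t = cf[, 3], p = cf[, 4],
                              row.names = NULL, stringsAsFactors = FALSE),
    r_squared = summary(fit)$r.squared,
    residual_df = stats::df.residual(fit), fit = fit),
    class = "trait_model_fit")
}

model_frame <- function(trait, table, species_mode) {
  if (!trait %in% names(table))
    stop("trait '", trait, "' not found in table", call. = FALSE)
  d <- data.frame(
    y = table[[trait]],
    group = factor(if (species_mode == "type") table$plant_type
                   else table$species),
    elev_c = table$elevation_m - mean(table$elevation_m))
  d[is.finite(d$y), , drop = FALSE]
}

#' Per-type elevation regressions for a trait
#'
#' Intended as the follow-up when the type x elevation interaction is
#' significant: one simple regression of the trait on elevation per plant
#' type, with a slope confidence interval. When the pooled model's
#' interaction p-value is at or above `gate_p`, the pooled model is
#' retained and reported as such.
#'
#' @inheritParams fit_trait_model
#' @param gate_p Interaction p-value below which per-type fits are made.
#' @param conf_level Confidence level of the slope interval.
#' @return A list of class `by_group_fit`: `pooled_retained` (logical),
#'   `interaction_p`, and (when fitted) `fits` — a data.frame with one
#'   row per plant type: slope, SE, confidence bounds, p and n. Types
#'   with fewer than 3 points are skipped with a warning.
#' @export
fit_by_group <- function(trait, table, gate_p = 0.05, conf_level = 0.95) {
  pooled <- fit_trait_model(trait, table)
  ip <- pooled$anova$p[pooled$anova$term == "group:elevation"]
  if (is.na(ip) || ip >= gate_p)
    return(structure(list(trait = trait, pooled_retained = TRUE,
                          interaction_p = ip, fits = NULL),
                     class = "by_group_fit"))
  rows <- list()
  for (type in PLANT_TYPES) {
    sub <- table[table$plant_type == type & is.finite(table[[trait]]), ,
                 drop = FALSE]
    if (nrow(sub) < 3L) {
      warning("plant type '", type, "' has < 3 points; skipped")
      next
    }
    f <- stats::lm(sub[[trait]] ~ sub$elevation_m)
    cf <- summary(f)$coefficients
    ci <- stats::confint(f, level = conf_level)
    rows[[type]] <- data.frame(
      plant_type = type, slope = cf[2, 1], se = cf[2, 2],
      conf_low = ci[2, 1], conf_high = ci[2, 2], p = cf[2, 4],
      n = nrow(sub), stringsAsFactors = FALSE)
  }
  structure(list(trait = trait, pooled_retained = FALSE,
                 interaction_p = ip,
                 fits = do.call(rbind, c(rows, make.row.names = FALSE))),
            class = "by_group_fit")
}

#' Rank-based inverse-normal transform
#' @param x Numeric vector (NAs preserved).
#' @return Transformed vector with approximately standard-normal ranks.
#' @export
rankit <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- is.finite(x)
  n <- sum(ok)
  out[ok] <- stats::qnorm((rank(x[ok], ties.method = "average") - 0.5) / n)
  out
}

#' Trait-environment simple regressions
#'
#' One ordinary least-squares regression per trait x environment variable,
#' joining the per-band environment table to samples by elevation band.
#' Traits are transformed toward normality first (default: rank-based
#' inverse normal).
#'
#' @param table Trait table.
#' @param env Environment data.frame with an `elevation_m` column plus
#'   numeric environment variables.
#' @param transform `"rankit"` (default), `"log"` (log of positive
#'   values) or `"none"`.
#' @param catalog Trait catalog.
#' @return A data.frame with one row per (trait, env variable): `slope`,
#'   `intercept`, `r_squared`, `p`, `n`. Constant environment variables
#'   are skipped with a warning.
#' @export
env_regressions <- function(table, env,
                            transform = c("rankit", "log", "none"),
                            catalog = default_catalog()) {
  transform <- match.arg(transform)
  if (!"elevation_m" %in% names(env))
    stop("environment table must have an elevation_m column", call. = FALSE)
  idx <- match(table$elevation_m, env$elevation_m)
  if (anyNA(idx))
    stop("sample elevation band(s) absent from environment table: ",
         paste(unique(table$elevation_m[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  vars <- setdiff(names(env), "elevation_m")
  vars <- vars[vapply(env[vars], is.numeric, logical(1))]
  codes <- trait_codes(table, catalog)
  tf <- switch(transform,
               rankit = rankit,
               log = function(x) ifelse(x > 0, log(x), NA_real_),
               none = identity)
  rows <- list()
  for (v in vars) {
    xv <- env[[v]][idx]
    if (stats::sd(xv, na.rm = TRUE) == 0 || !is.finite(stats::sd(xv, na.rm = TRUE))) {
      warning("constant environment variable skipped: ", v)
      next
    }
    for (code in codes) {
      y <- tf(table[[code]])
      ok <- is.finite(y) & is.finite(xv)
      if (sum(ok) < 3L) next
      f <- stats::lm(y[ok] ~ xv[ok])
      cf <- summary(f)$coefficients
      rows[[length(rows) + 1L]] <- data.frame(
        trait = code, env_var = v, slope = cf[2, 1],
        intercept = cf[1, 1], r_squared = summary(f)$r.squared,
        p = cf[2, 4], n = sum(ok), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
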