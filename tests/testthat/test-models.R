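test_that("an exact linear elevation trend yields p ~ 0 and no interaction", {
  ds <- generate_dataset(null_config(41))
  tab <- ds$traits
  tab$LDMC <- 2 + 0.004 * tab$elevation_m   # exact, no noise
  fit <- suppressWarnings(fit_trait_model("LDMC", tab))
  an <- fit$anova
  expect_lt(an$p[an$term == "elevation"], 1e-12)
  # interaction carries only floating-point rounding, not real signal
  tot <- sum(an$sum_sq)
  expect_lt(an$sum_sq[an$term == "group:elevation"] / tot, 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)
})

test_that("sequential SS decompose the total sum of squares", {
  for (seed in c(3, 14, 15)) {
    ds <- generate_dataset(synthetic_config(seed = seed,
      type_offsets = c(LC = 0.8), elevation_slopes = c(LC = 1)))
    fit <- fit_trait_model("LC", ds$traits)
    tot <- sum((ds$traits$LC - mean(ds$traits$LC))^2)
    expect_equal(sum(fit$anova$sum_sq), tot, tolerance = 1e-8)
  }
})

test_that("F tests match brute-force nested-model comparisons", {
  ds <- generate_dataset(synthetic_config(seed = 88,
    type_offsets = c(RS = 0.5), interaction_slopes = c(RS = 1)))
  tab <- ds$traits
  d <- data.frame(y = tab$RS, g = factor(tab$plant_type),
                  e = tab$elevation_m - mean(tab$elevation_m))
  rss <- function(f) sum(resid(f)^2)
  m0 <- lm(y ~ 1, d); m1 <- lm(y ~ g, d); m2 <- lm(y ~ g + e, d)
  m3 <- lm(y ~ g + e + g:e, d)
  an <- fit_trait_model("RS", tab)$anova
  dfr <- df.residual(m3)
  # sequential F uses the full-model residual mean square as denominator
  expect_equal(an$F[1], ((rss(m0) - rss(m1)) / 1) / (rss(m3) / dfr),
               tolerance = 1e-8)
  expect_equal(an$F[2], ((rss(m1) - rss(m2)) / 1) / (rss(m3) / dfr),
               tolerance = 1e-8)
  expect_equal(an$F[3], brute_force_f(rss(m2), rss(m3), 1, dfr),
               tolerance = 1e-8)
})

test_that("type-II tests adjust each main effect for the other", {
  ds <- generate_dataset(synthetic_config(seed = 19,
    type_offsets = c(LN = 1), elevation_slopes = c(LN = 2)))
  tab <- ds$traits
  an2 <- fit_trait_model("LN", tab, ss = 2)$anova
  d <- data.frame(y = tab$LN, g = factor(tab$plant_type),
                  e = tab$elevation_m - mean(tab$elevation_m))
  rss <- function(f) sum(resid(f)^2)
  full2 <- lm(y ~ g + e, d)
  expect_equal(an2$F[1],
               brute_force_f(rss(lm(y ~ e, d)), rss(full2), 1,
                             df.residual(full2)), tolerance = 1e-8)
})

test_that("singular designs are rejected with an informative error", {
  ds <- generate_dataset(null_config(2))
  one_type <- ds$traits[ds$traits$plant_type == "ephemeral", ]
  expect_error(fit_trait_model("LC", one_type), "group")
  one_band <- ds$traits[ds$traits$elevation_m == 600, ]
  expect_error(fit_trait_model("LC", one_band), "elevation")
})

test_that("per-type refits recover planted slopes of opposite sign", {
  cfg <- synthetic_config(seed = 57, species_sd = 0, noise_sd = 0.3,
                          n_replicates = 20L,
                          elevation_slopes = c(RP = -2),
                          interaction_slopes = c(RP = 4))
  # ephemeral slope = -2 + 4 = +2 per km; non-ephemeral slope = -2 per km
  ds <- generate_dataset(cfg)
  bg <- fit_by_group("RP", ds$traits)
  expect_false(bg$pooled_retained)
  slopes <- stats::setNames(bg$fits$slope * 1000, bg$fits$plant_type)
  expect_equal(unname(slopes["ephemeral"]), 2, tolerance = 0.5)
  expect_equal(unname(slopes["non_ephemeral"]), -2, tolerance = 0.5)
})

test_that("without interaction the pooled model is retained", {
  ds <- generate_dataset(null_config(66))
  bg <- fit_by_group("SLA", ds$traits)
  expect_true(bg$pooled_retained)
  expect_null(bg$fits)
})

test_that("environment regressions recover a constructed dependence", {
  ds <- generate_dataset(null_config(12))
  tab <- ds$traits
  env <- default_environment()
  mat <- env$MAT[match(tab$elevation_m, env$elevation_m)]
  tab$LTFC <- 3 - 2 * mat + rnorm(nrow(tab), 0, 1e-4)
  er <- env_regressions(tab, env, transform = "none")
  row <- er[er$trait == "LTFC" & er$env_var == "MAT", ]
  expect_gt(row$r_squared, 0.999)
  expect_lt(row$slope, 0)
  env2 <- env; env2$soil_P <- 0.1
  expect_warning(env_regressions(tab, env2, transform = "none"), "soil_P")
})

test_that("rank-based inverse normal transform yields normal-ranked scores", {
  x <- rexp(200)
  z <- rankit(x)
  expect_equal(mean(z), 0, tolerance = 1e-8)
  expect_equal(order(z), order(x))
  expect_gt(stats::shapiro.test(z)$p.value, 0.9)
})
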