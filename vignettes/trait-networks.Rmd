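---
title: "Trait comparisons, phylogenetic signal and trait networks along elevation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait comparisons, phylogenetic signal and trait networks along elevation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitnet)
```

## The scientific setting

Spring ephemeral herbs emerge after snowmelt, flower, fruit and go dormant
before the forest canopy closes; spring non-ephemerals emerge at a similar
time but keep growing into early fall. The two life histories imply
different trade-offs between growth and defense, and those trade-offs leave
signatures in plant functional traits and — importantly — in the
*correlation structure among* traits. `traitnet` implements the complete
analysis chain for such a study design: quadrat-survey importance values,
per-trait two-group comparisons with a normality gate, PCA, linear models
of each trait on plant type, elevation and their interaction, Blomberg's K
as a measure of phylogenetic signal, and thresholded Spearman plant trait
networks (PTNs).

The package works with a fixed catalog of 26 functional traits
(`default_catalog()`), split into 7 economic traits (leaf structure and
leaf stoichiometry: LDMC, SLA, LC, LN, LP, LC_N, LN_P), 11 nutrient traits
(root stoichiometry and leaf/root carbohydrates: RC, RN, RP, RC_N, RN_P,
LSS, LS, LNSC, RSS, RS, RNSC) and 8 defensive traits (cellulose, lignin,
phenols, flavonoids in leaf and root: LCC, LLC, LTPC, LTFC, RCC, RLC,
RTPC, RTFC). Ratio traits use an underscore (`LC_N` is the leaf C:N
ratio) so that codes are valid column names in every table the package
reads or writes. Units in the catalog are free-text metadata; no
conversion is ever applied.

## Importance values

`importance_value()` computes, per species,

IV = (relative frequency + relative density + relative coverage) / 3,

where frequency counts occupied quadrats, density sums individual counts,
coverage sums cover fractions, and each component is normalized to sum to
one over species. The sampling unit for the frequency component is the
quadrat by default; a `frequency_unit = "plot"` switch counts occupied
plots instead, since survey protocols differ on this point. Height is
often recorded in such surveys but does not enter IV. Each component and
the IV vector are simplex-valued, and IV is invariant to rescaling all
covers by a constant; the degenerate all-zero-cover case sets the coverage
component to zero for every species and flags the result.

## Two-group comparisons with a normality gate

`compare_trait()` first applies a Shapiro–Wilk gate per group
(`normality_gate()`): only when both groups fail to reject normality at
the gate level (default 0.05) is a parametric test used; otherwise a
two-sided Mann–Whitney test on all values, exact for combined n ≤ 20
without ties and normal-approximated with tie correction otherwise. The
gate is applied per group rather than to the pooled sample, because
pooling two shifted groups can mask non-normality within each. The
parametric branch is a *paired* t-test on elevation × replicate matched
group means: elevation band is the stratum the two plant types share, so
pairing on it removes band-to-band variation; an `"unpaired"` pairing
strategy (Welch) is available, and the paired branch falls back to
unpaired with a warning when no matched pairs exist. A
Benjamini–Hochberg-adjusted column is emitted for reference, but per-trait
decisions use raw p-values.

`standardize_traits()` centers and scales each trait (sample sd, n − 1),
dropping zero-variance traits with a warning, and `trait_pca()`
eigendecomposes the resulting correlation structure. Components are
ordered by variance explained, which sums to one; each component's sign
is fixed so its largest-magnitude loading is positive, making outputs
reproducible across platforms.

## Linear models along elevation

`fit_trait_model()` fits, per trait, an ordinary least squares model

trait ~ group + elevation + group × elevation

with elevation continuous in meters (centered at its mean for numerical
stability only; F statistics are unaffected). "Group" is the two plant
types by default; `species_mode = "species"` uses the eight species as an
8-level factor instead. F-tests use sequential (type-I) sums of squares in
the stated order — the default of the common statistical environments for
this kind of model — with type-II available via `ss = 2`, implemented as
nested-model RSS comparisons. When the interaction is significant
(`fit_by_group()`, gate at p < 0.05), one simple regression per plant type
is fitted with a slope confidence interval; otherwise the pooled model is
retained and reported as such.

`env_regressions()` regresses each trait on each site-level environment
variable (soil pH, C, N, P, EC, and mean annual temperature,
precipitation, solar radiation), joining per-band environment records to
samples by elevation band. Traits are first transformed toward normality;
the default is the rank-based inverse-normal (rankit) transform, chosen
because it is monotone, assumption-light and well-defined for every trait
regardless of sign or skew; `"log"` and `"none"` are available.

## Blomberg's K and its permutation null

For a trait vector x over the tips of a rooted tree with branch lengths,
with C the Brownian-motion covariance (shared root-to-tip path lengths,
`phylo_vcv()`) and â the GLS ancestral mean,

K = [MSE0 / MSE] / E[MSE0 / MSE], with
MSE0 = (x − â)ᵀ(x − â)/(n − 1), MSE = (x − â)ᵀC⁻¹(x − â)/(n − 1),
E[MSE0/MSE] = [tr(C) − n/(1ᵀC⁻¹1)]/(n − 1).

K = 1 is the Brownian expectation, K < 1 weaker and K > 1 stronger signal
than Brownian motion. On a star tree C is proportional to the identity and
K equals 1 exactly for any trait vector — a useful analytic identity that
the test suite checks to 1e-10. Significance comes from shuffling trait
values across tips (`permutation_test_k()`, default 999 shuffles) with the
add-one correction p = (1 + #{K⁰ ≥ K}) / (n_perm + 1), so p is never zero
and has resolution 1/1000 at 999 shuffles. Replicates are collapsed to
species means before K because the tree carries one tip per species; the
collapse function is configurable. C is solved, not explicitly inverted,
and a condition number above 1e12 raises an error rather than silently
regularizing. Polytomies and zero-length internal branches are accepted.

## Plant trait networks

`spearman_matrix()` computes pairwise Spearman correlations with
average-rank tie handling and pairwise deletion; two-sided p-values use
the t approximation with df = n − 2, switching to the exact rank-statistic
null below 10 complete pairs when ties permit. Pairs with fewer than 5
complete observations are flagged missing and can never become edges.
`binarize()` draws an edge where |ρ| > 0.2 *and* p < 0.05, both strict
inequalities, matching the threshold rule read literally; whether to
multiplicity-adjust the p matrix first is an open methodological point —
raw p is the default here, and the BH-adjusted comparison column is
available from the comparison stage for sensitivity checks.

`network_metrics()` reports degree, edge density E/(n(n−1)/2), Newman's
modularity Q of a community partition, mean shortest-path length over
connected pairs (with an explicit disconnectedness flag, since thresholded
networks are often disconnected), and the per-category relative importance
RI = (mean degree of the category) / (sum of all degrees).

Community detection is fully deterministic, because Q values that change
across runs are useless for comparing strata. The search combines
CNM-style greedy agglomeration (ties broken toward the lowest-labelled
pair), recursive leading-eigenvector bisections as additional starting
partitions, and a refinement stage of Kernighan–Lin node-move passes
interleaved with exhaustively optimal bipartitions of single communities
and of pairwise community unions (enumerated exactly up to 14-node sets).
On graphs small enough for complete enumeration the package also ships an
independent exhaustive oracle (`exhaustive_modularity()`, restricted
growth strings over all set partitions); the suite verifies that the
deterministic search attains the enumerated optimum on hundreds of random
connected graphs with up to 8 nodes, and that two disjoint K4 cliques
yield the planted bipartition with Q = 0.5 exactly. On 26-node trait
networks the search is a strong heuristic; reported Q is always the Q of
the returned partition, never an upper bound.

`compare_networks()` builds one network per stratum — the two plant
types, or the three elevation bands — from that stratum's samples pooled
across the other factor, and reports metrics side by side with a
degree-sorted hub table.

## The synthetic generator and what it does (not) show

No raw measurements are distributed with this design, so
`generate_dataset()` provides study-shaped data with known ground truth:
8 species (4 ephemeral, 4 non-ephemeral, the study's species set by
default) × 3 elevation bands (600/800/1000 m) × `n_replicates` samples of
all 26 traits, plus a tree and a per-band environment table whose values
follow the published site summaries. The replicate default is 3 pooled
samples per species × band — the field protocol pools several individuals
per sample and does not fix the count, so this is a free parameter chosen
once.

The generating model, per trait:

- a species-level component `species_sd · (√λ · z_BM + √(1−λ) · z_iid)`,
  blending a standardized Brownian draw on the tree with standardized
  white noise. λ tunes phylogenetic signal monotonically; it does not
  target an exact K, because K has no closed-form inverse, and tests
  assert monotonicity and calibration (mean K ≈ 1 at λ = 1), not exact
  values. Setting `species_sd = 0` removes between-species structure
  entirely, which is the correct null for level checks: with only 8
  species, any nonzero species variance induces cross-trait sample
  correlations of order 1/√7 and clusters samples within species, so
  "no planted effects" must mean no species-level variance at all.
- fixed effects: a type offset (added to ephemerals), an elevation slope
  and an interaction slope, both per kilometer so magnitudes stay O(1).
- replicate-level residuals scaled by `noise_sd`; traits within one
  planted module share a latent factor with loading ρ, giving
  within-module pairwise correlation ρ² and zero between-module
  correlation by construction — exactly the structure the thresholded
  Spearman network should recover.

Everything is reproducible: a fixed config (including its seed) yields a
byte-identical dataset, and the echoed `truth` record carries every
planted parameter.

What the generator does not emulate: instrument-specific assay noise,
spatial autocorrelation among plots, missing-data patterns, and the
co-occurrence of phylogenetic signal with module structure in the same
trait set. Passing tests on synthetic data therefore demonstrate that the
estimators recover what was planted under clean conditions — not that any
particular field dataset satisfies those conditions.

## Problem sizes and numerical choices

The calibration suite uses sizes chosen to make Monte-Carlo error small
relative to the asserted tolerances: 500 Brownian replicates on a 32-tip
tree for the K calibration (mean K within [0.9, 1.1]); 100 random vectors
for the star-tree identity at 1e-10; 20 random connected graphs with 4–8
nodes against the exhaustive modularity oracle; module recovery at ρ =
0.85 with 50 replicates per species × band (1,200 samples), requiring
adjusted Rand agreement above 0.8 and a between-module false-edge rate of
at most 7% under the |ρ| > 0.2, p < 0.05 rule; and 1,000 fully-null
datasets × 6 probe traits (6,000 tests per statistic) for the 5% ± 1.5%
type-I checks of both the gated comparisons and the three model F-tests.

Numerical conventions worth knowing: strict inequalities at both network
thresholds; community labels densely renumbered in order of first
appearance; degree ties in hub tables broken by trait label; Q compared
with a 1e-12 tolerance internally so floating-point noise cannot flip a
merge decision; Shapiro–Wilk failures on degenerate (constant or n < 3)
groups gate to the nonparametric branch; missing trait values are
explicit `NA`s, handled pairwise in correlations and listwise in models
and PCA.

## Known limitations

- The greedy modularity search is exact-verified only against graphs small
  enough to enumerate; for 26-node networks it is a (deterministic)
  heuristic, and published modularity values from other algorithms need
  not match it.
- The paired t-test branch defines pairs by elevation × replicate matched
  group means; other pairing designs are reasonable and change the test's
  power profile.
- Environment regressions treat band-level environment values as exact,
  ignoring within-band variation.
- K is computed on species means; intraspecific variation is not
  propagated into the permutation null.
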