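---
title: "Corner-store supplier networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corner-store supplier networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cornernet)
```

## The problem

Corner stores in low-income urban neighborhoods stock what they can
conveniently and affordably procure. The set of suppliers a storeowner
actually uses — wholesale clubs, snack distributors, beverage companies,
supermarkets — therefore constrains what ends up on the shelf. `cornernet`
models storeowner-reported purchasing as a pair of two-mode (bipartite)
store–supplier networks and asks how the *healthy* supplier network (HSN)
differs from the *unhealthy* supplier network (UHSN), and which store
characteristics predict a store's connectedness to healthy suppliers.

The unit of evidence is a purchase record: store *s* acquired item *i* from
supplier *u*. Items are classified against a promoted-food catalog
(lower-calorie beverages, healthier essentials, healthier snacks versus
snack-food staples higher in salt, fat, and sugar). An edge (s, u) enters
the HSN when at least one healthy-classified purchase witnesses it, and the
UHSN when at least one unhealthy-classified purchase does. The two networks
are deliberately not mutually exclusive: a wholesaler selling both soda and
bananas to the same store sits in both. Items absent from the catalog are
reported as *unknown* and excluded from both networks — classification is
catalog membership, never a nutrient model.

## Network measures

All measures treat ties as binary; purchase frequency is recorded but never
weights an edge, since a single sourcing relationship is the quantity of
interest.

**Degree centrality (two-mode).** A store's raw degree is its number of
distinct supplier connections; the normalized version divides by the number
of suppliers *in that network* — the HSN and UHSN denominators differ — and
is reported as a percentage. Stores with no ties stay in the table at 0%.

**Network core.** Suppliers are ranked by degree, descending, with ties
broken by identifier so the ranking is reproducible. The core is the
shortest prefix of the ranking whose summed degrees cover at least 80% of
the network's edges (threshold configurable in (0, 1]). This is a
deterministic cumulative-coverage rule, not a block-model core–periphery
fit; the two can disagree, and no block-model claim is made.

**Diversity.** The number of distinct supplier categories (of the
seven-level Standard Industrial Classification food-store taxonomy) among a
store's neighbors, from 0 to 7.

**One-mode projection and density.** Two stores are adjacent in the
projection when they share at least one supplier; the weight records how
many they share. Density dichotomizes those weights: 100 × |edges| /
(n(n−1)/2). Isolated stores remain in the denominator, so density reads as
cohesion of the whole store sample, and the shared-supplier summary
(mean/min/max of positive weights, isolate count) is reported alongside.

## Comparison statistics

**Centrality comparison.** The default is a paired t-test across stores —
the same 24 stores appear in both networks, so pairing is the natural
design. Pooled-variance and Welch independent tests are selectable because
the pairing assumption, while natural, is not forced by the data layout.
Differences are oriented UHSN − HSN throughout. Two degenerate cases are
distinguished: identical tables return t = 0, p = 1 (no difference, no
evidence), while a constant nonzero difference with zero variance is
flagged rather than given an infinite statistic.

**Density comparison.** Densities of two one-mode networks are compared
with a node-resampling bootstrap: resample each network's stores with
replacement, recompute the density of the induced dyads (pairs formed by
two copies of the same store carry no tie information and are imputed at
the observed density), and read off the spread. Node resampling duplicates
dyad (u, v) with clustered multiplicity c_u·c_v, which inflates the raw
bootstrap spread relative to the true sampling error of density; the spread
is therefore deflated by the exact multinomial factor sqrt(Var(c_u c_v)),
which approaches sqrt(3) as n grows. After this correction the estimator is
calibrated for dyad-independent graphs — simulations in the test suite put
the empirical type-I error at 0.03–0.05 for 24-store networks at nominal
0.05. For graphs with strong dyadic dependence the correction is
approximate; that limitation is inherited from treating density as a mean
of exchangeable dyads. The statistic (d_A − d_B)/sqrt(se_A² + se_B²) is
referred to a t distribution on n_A + n_B − 2 degrees of freedom. The seed
is a required argument: two runs with the same seed agree to machine
precision.

**Bivariate regressions.** Nine store characteristics (mean distance to
connected suppliers, WIC and SNAP acceptance, owner ethnicity, two tenure
measures, daily customers, and two employee counts) are regressed one at a
time on degree centrality, in both networks, echoing a small-sample design
(n = 24) in which multivariate adjustment is not supportable. The default
outcome is the raw degree, so slopes read as "connections"; the normalized
percentage is available by flag. Ethnicity is coded with African American
storeowners as the reference level.

The slope is ordinary least squares in all cases. For the *interval*, the
package defaults to the Bell–McCaffrey construction: the
heteroskedasticity-consistent HC2 variance with Satterthwaite degrees of
freedom, which for a binary covariate reduces to a Welch interval. The
reason is structural: degree counts are sums of Bernoulli tie indicators,
so their variance differs systematically between covariate groups, and with
a heavily unbalanced binary covariate (21% vs 79% for ethnicity) the
classical homoskedastic interval undercovers badly — in simulations under
this package's own generator its 95% interval covers the true effect only
~80% of the time, while the Bell–McCaffrey interval covers ~95%. The
classical interval remains available (`se = "classical"`) for comparability
with legacy analyses. When a leverage-one observation makes HC2 undefined
(a singleton covariate group), the classical interval is used and labelled.
No multiple-testing correction is applied by default, matching the
bivariate screening design; a Benjamini–Hochberg flag exists.

**Sensitivity analysis.** All regressions are re-run after deleting
purchases from delivering suppliers, leaving only self-supply trips — the
subset for which travel distance is a live constraint.

## Distances

Store-to-supplier distance is the great-circle (haversine) distance on a
sphere of radius 6371.0088 km. Suppliers may have several distribution
sites; the site nearest the store is chosen per edge, and the per-store
covariate is the mean over that store's *connected* suppliers in the
network under analysis. Haversine versus a road network understates true
travel, but road routing is out of scope; coordinates are inputs, not
geocoded addresses.

## The synthetic generator

No store–supplier edge list is publicly available at the individual level,
so the generator exists to produce datasets with the statistical structure
the analysis assumes, at the study's scale. Its defaults are the study
conditions:

* 24 stores; 42 suppliers in the seven categories (11 wholesale clubs, 10
  snacks, 4 specialty foods, 5 beverages, 9 supermarkets/groceries, 2
  discount department stores, 1 meat market).
* Store covariates drawn to match the reported sample: WIC acceptance
  45.8%, SNAP 91.7%, 79% Asian/Hispanic owners, tenure 9.5 ± 7.7 and
  15.6 ± 9.1 years (total tenure floored at current-store tenure),
  165 ± 145 daily customers, Poisson employee counts with means 0.75 and
  1.96. Coordinates are uniform in a Baltimore-sized bounding box — no
  spatial clustering is attempted.
* Ties are Bernoulli, independent per (store, supplier, class):
  unhealthy-tie probability 0.215 (so mean normalized UHSN centrality sits
  near 21.5%), healthy-tie baseline 0.117 for the reference group.
* Covariate effects are additive shifts in *expected healthy raw degree*
  (ethnicity −1.5 connections, SNAP −1.9, WIC 0 by default), applied to the
  healthy network only, and spread uniformly over the healthy-capable
  suppliers.

Which suppliers are healthy-capable follows the product structure of the
observed rosters: wholesale clubs, supermarkets, and discount stores carry
the full healthy range; beverage companies carry the lower-calorie
beverages (bottled water, diet soda); two snack suppliers carry a baked
snack and one specialty supplier carries whole-wheat bread; the meat market
carries none. That gives 30 of 42 healthy-capable suppliers, which matters
for feasibility: the combined default effects (−3.4 connections) spread
over 30 suppliers keep every per-supplier probability nonnegative
(0.117 − 3.4/30 ≈ 0.004), so expected degrees shift by exactly the
configured effects with no clamping. Configurations that do drive a
probability outside [0, 1] are clamped with a warning, at the cost of
biasing the realized effect.

What the generator does **not** emulate: dyadic dependence (reciprocity,
popularity spill-over) — ties are independent given covariates; seasonal or
longitudinal dynamics; correlated covariates (WIC, SNAP, and ethnicity are
drawn independently); realistic spatial placement; and item-level
purchasing frequency beyond a decorative Poisson count. Tests passing on
generated data therefore validate the pipeline's arithmetic and its
statistical calibration under independence, not robustness to network
dependence in field data.

One consequence worth stating plainly: under the default effects, most
stores (Asian/Hispanic owners accepting SNAP, ~72% of draws) sit near zero
expected healthy degree, so the generated HSN is sparser than the published
one — at some seeds no two stores share a healthy supplier and the HSN
density is 0%. The defaults reproduce the configured tie rates and effects,
not the published aggregate network statistics; those aggregates were never
jointly attainable from the published marginal figures.

## Numerical and interface choices

* Item names are canonicalized (trim, collapse internal whitespace,
  lowercase) before catalog lookup; catalogs reject items mapped to both
  classes.
* Supplier rosters are counted under two conventions — multiplicity-expanded
  *entries* and name-collapsed *distinct* — because the packaged roster
  uses both (a chain listed once with a multiplicity-2 annotation). Both
  counts are always reported rather than privileging either.
* Core extraction requires at least one edge and a threshold in (0, 1];
  centrality on an edgeless network returns raw zeros with a flagged,
  NA-normalized table.
* Density requires at least two stores. The shared-supplier mean is
  undefined (NA) on an edgeless projection.
* All randomness (generator, bootstrap) flows from explicit integer seeds;
  the report stage derives its bootstrap seed from the config seed, so a
  full report run is byte-reproducible.
* Graph exports use GraphML via igraph (node roles, core tags, edge
  weights) or a weighted edge-list CSV; re-import reproduces node and edge
  sets exactly.

## Problem sizes used in the test suite

Oracle-equivalence tests run brute-force checks on 100+ random bipartite
graphs up to 10 × 10. Calibration tests use 400 replicates each for the
bootstrap test's null rejection rate (24-store networks, 300 resamples) and
for coverage of the configured ethnicity effect at the default 24-store
configuration — sizes chosen to keep Monte-Carlo error a small fraction of
the acceptance bands.

## Known limitations

Binary ties discard sourcing frequency and spend; the coverage core is one
deterministic reading of "suppliers covering 80% of connections" and not a
fitted core–periphery partition; the bootstrap density test's calibration
guarantee is exact only under dyad independence; haversine distance ignores
the road network; and the generator's independence assumptions mean
field-data inference should treat the regression intervals as
approximations, not guarantees.
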