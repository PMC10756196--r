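---
title: "Methods: time-varying matrix kinship projections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-varying matrix kinship projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinproj)
```

## The model

`kinproj` computes the expected kinship network of a female reference
individual (Focal), conditional on her being alive at each reported age.
Kin of every type are treated as small age-structured populations projected
with the same machinery as the population itself: a survival matrix `U`
with per-step survival probabilities on the subdiagonal, and a fertility
matrix `F` with age-specific rates in the first row. For kin type `k` with
recruitment source `src(k)`,

    k(x+1, t+1) = U_t k(x, t) + F_t src(k)(x, t),

where `x` is Focal's age in steps and `t` calendar time. Children are
recruited by Focal herself, grandchildren by the children, younger siblings
by the parents, and so on; ancestors (parents, grandparents,
great-grandparents) have no recruitment and are only initialized at
Focal's birth. The boundary conditions mix the kin arrays of prospective
parents over the age distribution π of parents of current newborns:
parents start as π itself, grandparents as the parents' parents mixed over
π, older siblings as the parents' children mixed over π, and so on down
the list in `kin_categories()`. Because the recruitment graph is acyclic,
one dependency-ordered pass per period suffices; there is no fixed-point
iteration.

Under time-invariant rates the whole network follows from one schedule
pair (`time_invariant_kinship()`); with a rate sequence the network is
marched forward in time (`time_variant_kinship()`), rebuilding the age-0
boundary each period from the contemporaneous kin arrays and the observed
population structure. The time-invariant network at the first year serves
as the initial condition, which amounts to assuming the first year's rates
had been operating long before. The influence of that assumption decays as
the projection proceeds, which is why the early decades of a projection
should be read with more caution than the later ones.

Kin counts are expectations of a branching superposition; no variance is
propagated within one rate trajectory. Uncertainty enters only through the
ensemble of rate trajectories, mirroring how probabilistic population
projections are reported.

## Two-sex model and the androgynous approximation

The two-sex variant stacks female and male kin into one block vector, with
block-diagonal survival (sex-specific schedules) and a fertility operator
in which kin of both sexes reproduce and births split between the sexes by
the fraction female at birth α (default 100/205, i.e. 105 male births per
100 female). Male age-specific fertility schedules are rarely available,
so male kin reproduce at the female rates — the androgynous approximation.

Kin accrue along both the matrilineal and the patrilineal line: the
parents vector holds mother and father (π for fathers is built from the
male population weighted by the androgynous schedule), siblings are
children of either parent, aunts/uncles are siblings of either parent.
Under per-birth random mating this implies sibling-type kin include
paternal half-siblings, and no halving of the fertility operator is
needed: a mother's and a father's later births are (almost surely)
distinct individuals.

The approximation has a known, quantifiable cost: in a population with a
male surplus at birth, the fertility-weighted male pool exceeds the female
pool by roughly the sex ratio at birth, so each man's realized fathering
rate is slightly below the female schedule. The kernel, which applies the
full androgynous rate to male kin, therefore slightly overstates
paternal-line kin; the test suite demonstrates the direction of this
effect against the microsimulation and verifies exact agreement in a
sex-symmetric regime (α = 0.5, equal survival), where the androgynous
model is exactly consistent with an individual-based population.

Ancestor counts obey hard bounds regardless of rates — at most 2 expected
living parents, 4 grandparents, 8 great-grandparents — which the suite
checks across 50 randomized regimes.

## Rates, grids and inputs

All schedules live on a common grid (default: 21 five-year classes, 0–4 …
100+, matching abridged demographic output) with the time step equal to
the class width. Rates are piecewise-constant within each step; no
interpolation is performed. Inputs travel as a long CSV with columns
`location, year, age_lower, sex, variable, value`, where `asfr` is the
annualized fertility rate (converted to per-step rates by multiplying by
the step width), `Lx` the life-table person-years column (per-step
survival `p[x] = L[x+1]/L[x]`, clipped to [0, 1]), and `population` the
counts used for the observed-π boundary and for regional weighting.
Validation is eager and complete at read time — missing blocks are errors,
never interpolated — and the projection code assumes valid inputs. The
open-ended age class absorbs no one (`p = 0`): kin leaving the grid die,
which matters only for extreme-age ancestors.

## Numerical choices

- The stable-equivalent population behind the time-invariant π is built
  from the dominant eigenvalue λ of the female Leslie matrix:
  `w[x] ∝ l(x) λ^{-x}` per sex, with survivorship `l` from the sex's own
  schedule. If the schedule has no growth (zero fertility everywhere the
  eigenvalue degenerates to 0), λ falls back to 1, leaving a
  survivorship-weighted structure; π itself is then an error — a network
  without births has no mothers' distribution, and the package treats that
  as an error, not a NaN.
- π is normalized to sum to one within 1e-12; deterministic identities
  (constant-rates limit, closed-form children) hold to 1e-10 in the test
  suite and in practice to machine precision.
- Ensemble summaries use the standard linear-interpolation quantile
  (type 7) for the median and the 10th/90th percentiles; this choice is
  fixed and recorded here because different quantile estimators move
  interval endpoints by a visible amount at small ensemble sizes.
- Focal ages are reported at class lower bounds ("65" means the class
  65–69), and a year label denotes its five-year interval.

## The synthetic-rate generator

`make_fertility()` produces a unimodal schedule (scaled beta density over
ages 10–55) normalized so the per-step rates sum exactly to the total
fertility rate, with the requested mean age at childbearing (years) and
spread (standard deviation, years). `make_mortality()` uses a
Gompertz–Makeham hazard `h(a) = M + C e^{βa}`; `C` is calibrated by
root-finding so life expectancy at birth matches the target within 0.25
years, and per-step survival comes from the integrated survivor curve.
Defaults (slope 0.11 per year, background 0.0015 per year, female–male e0
gap 4 years) are in the range of fitted human schedules.

A location's history is a logistic transition between a start and an end
parameter set (`trend_params()`): midpoint year, speed in years, and a
population scale used when converting the period-stable structure into
counts. Stochastic futures (`sample_trajectories()`) branch after a
"present" year (default 2020, mirroring the split between historical
estimates and projections): seeded random walks perturb log-TFR and the
log mortality gap `log(110 − e0)`, so trajectories fan out with horizon
while life expectancy stays bounded, and every trajectory is rebuilt into
a fully valid rate series. The ensemble is a pure function of (parameters,
seed). The walk is deliberately simpler than the hierarchical Bayesian
models behind real probabilistic projections: the pipeline only needs a
widening, reproducible fan of valid schedules, not a calibrated forecast.

The bundled two-country world (`demo_world_params()`) contrasts a
high-fertility population going through a steep transition ("Alta", TFR
6.5 → 1.8, e0 45 → 78) with an already low-fertility, long-lived one
("Bassa", TFR 2.3 → 1.5, e0 65 → 86). What passing tests on this world
show is that the pipeline reproduces the qualitative dynamics of the
demographic transition — shrinking, verticalizing, aging kinship networks
— not that any particular real country's values are matched: synthetic
schedules lack period shocks (wars, epidemics, baby booms), migration, and
the cross-country correlation structure of real projection ensembles.

## The microsimulation oracle

`simulate_genealogy()` is a brute-force check on the kernel: an
individual-based population under the same rates (founders from the stable
age distribution, Poisson births with expectation equal to the per-step
rate, Bernoulli survival, fathers sampled fertility-weighted in the
two-sex variant), whose pedigree `tally_kin()` walks to count each Focal's
living kin by type and age. Two conventions make the tally estimate
exactly what the recursions propagate:

- Same-cohort kin (a sibling born in Focal's own five-year birth step)
  belong to the *younger* array: the recursions recruit them through the
  parent's fertility term in the birth step itself.
- The recursions' boundary conditions snapshot the parents' kin arrays at
  the birth instant, while the simulation's integer clock ticks once
  between counting a mother and her newborn's cohort. A kin individual
  reached by `l` generational ascents is therefore evaluated at simulation
  time `t − l` (children at `t`, parents at `t − 1`, grandparents at
  `t − 2`, …).

With both in place the kernel is unbiased against the oracle, and the
acceptance check asks every kin-category total at Focal ages 0, 35 and 65
to lie within three Monte Carlo standard errors. The standard error used
is the larger of the empirical SE across Focals and the Poisson model SE
`sqrt(μ/n)`: for rare kin (great-grandparents of a 65-year-old under low
survival) the empirical spread degenerates to zero while the Poisson scale
remains the relevant one. Focals within one genealogy share kin, so the
empirical SE mildly understates sampling variability; at the tested scale
(2,000 founders, six-generation burn-in ≈ 34 steps, ≈ 2,000 Focals per
age) this is visible only as occasional |z| values near the boundary.

## Problem sizes

The test suite runs the oracle comparison at 2,000 founders with a
six-generation burn-in, the ancestor-bound battery over 50 regimes, and a
1,000-trajectory ensemble regeneration; the acceptance script projects
200-trajectory ensembles for both synthetic countries over 1950–2100.
These sizes were chosen so each stage's Monte Carlo error is well below
the effects being measured while a full run stays in the minutes range on
one CPU.

## Limitations

Beyond the androgynous approximation discussed above: the model is closed
to migration; rates are age- and sex-specific only, so within-population
heterogeneity (education, parity, region) is invisible; kin counts are
expectations, not distributions — the probability of having *no* living
kin of a type is not computable from these outputs; socially fashioned
kin, spouses and in-laws are out of scope; and the time-invariant boundary
inherits whatever distortion affected the first year's rates.
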