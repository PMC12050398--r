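---
title: "Methods: trait-based analysis of Collembola communities"
author: "colltraits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-based analysis of Collembola communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colltraits)
```

# The problem and the data model

Springtails (Collembola) live stratified through the litter and upper
mineral soil, and their communities respond to forest composition both
taxonomically and functionally. The package analyses data from a replicated
forest-type design: plots nested in sites, each plot sampled by one Ø 5 cm
soil core separated into litter, 0–5 cm and 5–10 cm layers, all individuals
identified to species, and species annotated with traits (body length,
allometry group, life form, trophic guild, reproductive mode, pigmentation,
number of ocelli, furcal size, antenna/body ratio).

All plot-level analyses (richness per core, energetics, CWM, functional
diversity, ordination, PERMANOVA) use counts pooled over the three layers,
because those responses are defined per core or per plot; only the
species-level vertical-distribution trait uses the layer split, which is
exactly the information the split carries. Densities use the exact circular
core area `1/(π(d/2)²)` with no extraction-efficiency or edge correction —
none is defensible without calibration data.

# Energetics

Dry mass (µg) comes from group-specific length–mass power laws
(`DW = a·L^b`; Arthropleona a = 5.6, b = 2.693; Symphypleona a = 57.8,
b = 2.954 with the body length multiplied by 0.83), fresh mass from
`FM = 4.08·DW^1.02` (µg), and individual metabolic rate from
`I = i₀·M^0.759·e^(−E/(kT))` with i₀ = 3,477,995,118, E = 0.657 eV,
k = 8.62×10⁻⁵ eV K⁻¹, M fresh mass **in milligrams** and T the plot's mean
annual temperature in Kelvin. The µg→mg division by 1000 happens exactly
once, at the metabolic-rate call: the mass equations are defined in µg and
the rate equation in mg, so dimensional consistency forces this bridge even
though no source states it. Each species contributes at its single adult
body length — no juvenile size-class correction, since no size-distribution
procedure is available. Community metabolism is the density-weighted sum of
individual rates (J m⁻² h⁻¹); biomass likewise (mg m⁻²). Both are exactly
linear in densities, which the tests exploit.

# Trait metrics

Numeric traits are min-max scaled to [0, 1]; categorical traits become 0/1
indicator columns. A constant numeric column maps to all zeros instead of
being dropped so that column sets stay identical across simulated data sets.
Community-weighted means are `CWM_t = Σᵢ pᵢ·x_it` over relative abundances;
plots with zero captures are excluded and flagged rather than silently
dropped. The CWM of an indicator column equals the corresponding
abundance-weighted composition proportion — the package computes both
independently and the test suite asserts their exact agreement as an
internal consistency oracle.

The vertical-distribution score of a species is the abundance-weighted mean
of a numeric layer coding aggregated over **all** plots before weighting.
The default coding is surface affinity (litter = 1, 0–5 cm = 0.5,
5–10 cm = 0), so higher values mean more surface-living; a literal
midpoint-depth coding would only flip and rescale the axis, and the coding
is configurable. The scaled CWM of this score is min-max over plots.

# Functional diversity

Species dissimilarity is Gower distance over the standardized matrix with
**equal weight per source trait**: the indicator columns of one categorical
trait share its weight, so a categorical mismatch contributes exactly one
trait's worth. Principal-coordinates embedding of this matrix yields the
trait space; all positive-eigenvalue axes are retained (eigenvalues below
1e-8 of the largest are treated as zero), since Gower distances are
generally non-Euclidean and the negative axes are meaningless.

Functional evenness follows the minimum-spanning-tree formulation: branch
weights `EW = dist/(wᵢ+wⱼ)`, normalized to `PEW`, compared against the even
reference `1/(S−1)`. Functional divergence measures abundance-weighted
deviation of species distances from the gravity center of the convex-hull
vertex species. Both are undefined below three species with positive
abundance and are returned as `NA` with a reason, never silently as 0.
Both use the *global* trait space with *plot-level* abundances, matching
per-sample reporting of these metrics.

Convex-hull vertices in one or two dimensions use exact methods; in higher
dimensions each point is tested for membership in the hull of the others
with an away-step Frank–Wolfe projection, using the duality gap as a
certificate on both sides of the tolerance (distance > 1e-6 of the
configuration diameter ⇒ vertex). For more than eight retained axes the
hull uses the first eight principal axes to keep runtime at desk scale;
distances to the gravity center use the same axes for internal consistency.
Points on (but not strictly outside) a face are correctly classed as
non-vertices; vertices closer than the tolerance to the hull of the rest
may be absorbed, moving the gravity center negligibly.

Rarefaction uses the exact hypergeometric estimator
`Ŝ(m) = S − Σᵢ C(N−Nᵢ, m)/C(N, m)` for m ≤ N and extrapolates toward the
Chao1 asymptote (`f₀ = f₁²/2f₂`, or `f₁(f₁−1)/2` when f₂ = 0) beyond it.
Confidence bands are percentile bootstrap over individuals (default 200
resamples, seeded); the analytic variance of the estimator is deliberately
out of scope. The exact interpolation is cross-checked in tests against
both `vegan::rarefy` and brute-force Monte-Carlo subsampling.

# Multivariate inference

Bray–Curtis dissimilarities feed PERMANOVA with McArdle–Anderson
partitioning: sequential (type-I) sums of squares in the order
forest type, site condition, interaction — the stated model order, which
for the 40-plot design yields residual df 30 and a single df for site
condition. Permutations are free (unrestricted) by default because strata
handling is not determined by the design; explicit permutation matrices are
accepted, which the tests use for exhaustive 6-sample enumeration.
P-values use the add-one rule and can never be zero. Near-zero sums of
squares are clamped so that perfectly separated toys yield an infinite
pseudo-F rather than numerical noise. Species matrices are filtered to
species occupying more than one plot and Hellinger-transformed before PCA
by default (log1p and identity are available and recorded in the output);
PCA uses a deterministic sign convention (largest-magnitude loading
positive). Environmental variables pass a greedy collinearity filter
(|r| ≥ 0.8 drops the member of the worst pair with the larger mean absolute
correlation) before vector fitting onto the first two axes. Dispersion
homogeneity wraps the standard principal-coordinates distance-to-centroid
test.

# Univariate inference

Each response is fit by REML as
`y ~ forest_type * site_condition + (1 | site)` with beech as reference
level, after a per-response transform (log1p for abundance, biomass and
metabolism; square root for richness; none for bounded indices) — a
configuration choice, not automated selection. Marginal means average over
site condition; contrasts are treatment-vs-reference with no multiplicity
adjustment by default (mirroring per-contrast reporting; a familywise
option exists in `emmeans` if wanted). Degrees of freedom default to the
containment/between-within rule, computed as
`N − n_sites − rank(within-site fixed columns)` (= 24 for the full design);
the alternative is Satterthwaite via lmerTest rather than a plain normal
approximation, because it is strictly better and already installed with
the model machinery. Singular fits at the zero-variance boundary warn and
proceed.

# The synthetic-data generator

The generator is first-class, tested code that emulates the study
conditions: 8 sites (4 loamy southern, 4 sandy northern, latitudes
51.66–53.20° N, mean annual temperature near 281–283 K), 5 forest types per
site (40 plots, 120 layer samples), a 26-species pool with lognormal
relative abundances (σ = 1.5, giving top-five dominance near 80%), and
negative-binomial counts (size 5) — Poisson noise cannot produce the wide
confidence bands real cores show. Planted effects, all configurable:
spruce multiplies total expected abundance by 2.2; Douglas fir multiplies
euedaphic expectations by 0.4; mixtures apply half of each pure-conifer
effect; sandy sites retain each species with probability 0.7 and multiply
sexual-species expectations by 0.35. The beech baseline is 34 individuals
per core (≈ 17.3 × 10³ ind m⁻² at a loamy beech plot). Trait coupling makes
euedaphic species unpigmented, eyeless, short-furca and short-antenna, with
guild and reproductive mode correlated with life form but overlapping.
Individuals are allocated to layers multinomially by life form. Every
artifact draws from its own RNG stream derived from the master seed, so
regenerating one table never shifts another.

What the generator does *not* emulate: spatial structure within plots,
temporal dynamics, intraspecific trait variation, sampling-method biases,
and the empirical covariance between specific trait values and abundance.
Consequently, passing tests demonstrate that the *estimators recover
planted effects under the design's noise structure* — not that any
particular field community behaves like the simulation. Realized composite
quantities also drift from their back-of-envelope calibrations: the
loamy/sandy sexual-proportion ratio realizes near 1.5–2 rather than ~2.45,
because the abundance-weighted sexual share of a random pool sits below the
value assumed when the 0.35 multiplier was fixed; such values are reported
as computed, not recalibrated.

# Problem sizes and numerical choices

The test suite validates estimator calibration at the scales a desk run
affords: 200 replicates for mixed-model effect and variance-component
recovery, 500 null simulations for type-I error of PERMANOVA and of the
beech contrast (each checked against the binomial 95% CI around 0.05),
1000 random communities for metric-bound and CWM-consistency properties,
10,000 Monte-Carlo draws against the exact rarefaction formula, and
200-site generator runs for effect-recovery checks, where Monte-Carlo
error is a few percent of the planted effects. Permutation tests default
to 999 permutations; tests use fewer where only the statistic, not the
p-value resolution, is under scrutiny. Tolerances: 1e-10 relative for the
closed-form energetics chain, 1e-8 for eigendecomposition reconstructions,
add-one permutation p-values exactly.

# Known limitations

- Gower distance requires complete trait tables; there is no imputation.
- FDiv's Frank–Wolfe hull test is tolerance-based in > 2 dimensions (see
  above); exact hull libraries would remove the tolerance at the cost of a
  compiled geometry dependency.
- The PERMANOVA permutes freely; site-restricted permutation schemes are
  not implemented, only consistent reordering invariance is guaranteed.
- Back-transformed contrast ratios are reported for log-family transforms
  only; square-root contrasts stay on the model scale.
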