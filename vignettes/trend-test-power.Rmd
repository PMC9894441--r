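---
title: "Comparing trend tests for genotype association: models, simulation and theory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing trend tests for genotype association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genotrend)
```

## The data and the hypotheses

A case-control study at a diallelic marker yields the 2×3 table of case
counts (r₀, r₁, r₂) and control counts (s₀, s₁, s₂) over the genotypes
(aa, Aa, AA), ordered by copies of the minor allele A. Writing πᵢ for the
probability that a subject with genotype Gᵢ is a case, the null is
π₀ = π₁ = π₂ and the alternative is the ordered trend
π₀ ≤ π₁ ≤ π₂ (with at least one strict inequality), or its mirror image.
`GenotypeTable` is the container for these tables; margins are always
recomputed from the cells, so the margin identities R + S = N and
Σnᵢ = N cannot be violated by construction. Column order is a fixed
convention — ascending minor-allele count — and the package never
reorders silently: `minorAlleleFrequency()` warns when the pooled
frequency of A exceeds 0.5, the signature of a reversed table.

## The two test statistics

`caTrendTest()` implements the score-based Cochran-Armitage statistic.
The score vector (x₀, x₁, x₂), constrained to x₀ ≤ x₁ ≤ x₂ and x₀ < x₂,
is the analyst's stake in the ground about the mode of inheritance:
(0, 0.5, 1) additive, (0, 1, 1) dominant, (0, 0, 1) recessive
(`caScores()`). The statistic is invariant to positive affine changes of
the scores, so only their *shape* matters.

`jtTrendTest()` implements the Jonckheere-Terpstra statistic, which
replaces scores with ranks: U aggregates Mann-Whitney pairwise
comparisons of the binary phenotype between all pairs of genotype
groups. Because the phenotype takes only two values, the pairwise scores
collapse to a closed form over the six cell counts — each group pair
(i < k) contributes sᵢrₖ + 0.5(rᵢrₖ + sᵢsₖ) — so no individual-level
data are materialized and the cost is O(1) in N rather than O(N²). The
test suite proves the closed form equal to the individual-level triple
sum on random tables.

The null moments of U carry a tie correction for both tie sources: the
genotype group sizes nᵢ and the two phenotype groups of sizes R and S.
The variance is assembled from three components A, B and C as
Var(U) = A/72 + B/[36N(N−1)(N−2)] + C/[8N(N−1)]. This grouping of terms
is confirmed against an exhaustive oracle: for every margin
configuration with N ≤ 10, the closed-form E(U) and Var(U) equal the
mean and variance of U over all permutations of the phenotype labels to
within 10⁻⁹. T_JT = [U − E(U)]²/Var(U) is referred to χ²(1); the
reference is asymptotic, and when the smallest genotype group drops
below 5 subjects the result carries a caveat in its notes rather than a
hard cutoff, since no principled threshold exists.

Both tests are squared statistics, hence two-sided in the trend
direction; no continuity correction is applied anywhere. Both accept
*fractional* tables — non-integer cell values — which is deliberate and
load-bearing (see the theoretical comparison below). Degenerate inputs
fail loudly: a table with all weight on one score value, or with fewer
than two non-empty genotype groups, or with no cases or no controls,
raises an error naming the condition instead of returning NaN. In the
Monte-Carlo engine the same conditions are instead counted as
non-rejections and tallied, because discarding them would bias power
upward exactly in the small-N, rare-allele regime where they occur.

## The genetic model

`geneticModel(prevalence, maf, lambda, theta | thetaPrime | model)`
parameterizes the disease model by polar coordinates around the null
point (λ₁, λ₂) = (1, 1) of the genotype-relative-risk plane:
λ₁ = 1 + λ cos θ, λ₂ = 1 + λ sin θ. The arc θ ∈ [π/4, π/2] covers the
classical models — θ = π/4 dominant (λ₁ = λ₂), θ = arctan 2 additive
(λ₁ = (1+λ₂)/2, an exact identity of the parameterization), θ = π/2
recessive (λ₁ = 1) — and λ = 0 is the null regardless of θ. The angle
may be supplied in radians, as θ′ = θ/π ∈ [0.25, 0.5] (the natural
plotting axis), or as a preset name; radians are canonical internally.

Penetrances follow from the prevalence K: with Hardy-Weinberg genotype
frequencies P(G) = ((1−q)², 2q(1−q), q²), the baseline penetrance is
f₀ = K/[(1−q)² + 2λ₁q(1−q) + λ₂q²] and fᵢ = λᵢf₀, which enforces
ΣP(Gᵢ)fᵢ = K exactly. Hardy-Weinberg proportions in the population are
an assumption of this construction, not a theorem. The within-group
genotype probabilities are then Bayes inversions:
τᵢ = P(Gᵢ)fᵢ/K for cases, υᵢ = P(Gᵢ)(1−fᵢ)/(1−K) for controls; both
triples sum to 1 analytically, and the suite checks the normalization to
10⁻¹² over randomized parameter draws. Parameter combinations that push
a penetrance to 1 or beyond (large K, λ and q together) are rejected as
infeasible with the offending values named.

## Monte-Carlo power

`empiricalPower()` draws case counts from a trinomial(R, τ) and control
counts independently from trinomial(S, υ) — the model's own sampling
formulation — applies the requested tests, and reports the proportion of
replicates with p ≤ α plus the binomial standard error √(p̂(1−p̂)/reps).
The default design is balanced, R = floor(N/2), S = N − R, and the
default replicate count is 10,000 with 2,000 as the documented
desk-scale setting; the test suite runs one 10,000-replicate null
calibration (type-I error of both tests within [0.04, 0.06] at α = 0.05,
N = 500, q = 0.2) and 2,000-replicate checks elsewhere, sizes chosen so
the whole suite completes in well under a minute of simulation time.

Seeding is explicit everywhere: `empiricalPower()` seeds once from its
`seed` argument, and `powerCurve()` derives one deterministic sub-seed
per grid point (an affine map of the master seed, kept below 2³¹), so a
full curve is bit-reproducible and any single point can be recomputed in
isolation without re-running the rest.

For head-to-head comparison, `powerComparison()` applies both tests to
the *same* replicate tables and reports the power difference with its
paired standard error, sd(dᵢ)/√reps over the per-replicate rejection
differences dᵢ ∈ {−1, 0, 1}. The paired design matters: near power 1
(e.g. the dominant model at N = 1000, q = 0.3, where both tests exceed
0.98) the marginal standard errors are each larger than the true
difference, while the paired standard error — driven only by discordant
replicates — resolves the ordering comfortably at 2,000 replicates.

What the generator emulates, and what it does not: tables are drawn from
exactly the trinomial model with Hardy-Weinberg population frequencies,
a single diallelic locus, balanced design, no covariates, no genotyping
error and no population structure. Passing power checks therefore
demonstrate the statistical properties of the tests *under this model*;
they say nothing about confounding, stratification, differential
genotyping error or linkage structure in real cohorts, all of which the
real-data checks (Hardy-Weinberg per phenotype group, allelic-vs-trend
consistency) can only partially flag.

## Theoretical comparison on expected tables

Monte-Carlo noise can be removed entirely by evaluating both statistics
on the table of *expected* cell values E(rᵢ) = τᵢN/2,
E(sᵢ) = υᵢN/2 — a fractional table, which is why fractional mode is a
first-class contract of the test functions rather than an error. The
summary is ΔT = (T_JT − T_CA)/T_CA × 100%, computed by `deltaT()` and
swept over grids by `deltaTGrid()`; it is undefined at λ = 0, where both
statistics vanish, and the function says so rather than returning 0/0.
The default grid (K = 0.1, λ = 1, N ∈ {200, 500, 1000},
q ∈ {0.05, 0.1, 0.2, 0.3}, three models) reproduces the full published
comparison table: ΔT > 0 in every dominant cell (+2.15% to +12.03%),
|ΔT| < 2% in every additive cell, and ΔT < 0 in every recessive cell
(−27% to −69%). The suite asserts each of the 36 cells to two decimals
with an absolute tolerance of 0.01 percentage points: four additive
cells sit 0.005–0.008 points from the exact arctan-2 computation, a
last-digit artifact in the published rounding (evaluating the additive
column at the nearest 0.01 grid angle θ′ = 0.35, or at (λ₁, λ₂) =
(1.5, 2), moves the values by an order of magnitude more, ruling both
out as explanations).

One caveat the theory itself surfaces: at low MAF and small N under the
recessive model, the theoretical ΔT is negative yet the empirical power
difference is positive — the χ² approximation underlying the CA test
degrades exactly there, while the rank test makes no distributional
assumption. The package reports both quantities and does not attempt to
reconcile them.

## Supporting tests

`hweExactTest()` is the exact Hardy-Weinberg test: conditional on the
observed allele counts, the heterozygote count h has probability
proportional to 2ʰ/[((n_A−h)/2)! h! ((n_a−h)/2)!] over h of the parity
of n_A, and the two-sided p-value sums configurations no more likely
than the observed one — the standard convention; the likelihood-tie
comparison uses a relative tolerance of 10⁻⁷ so floating-point noise
cannot split exact ties. Probabilities are accumulated in log space,
keeping the test stable for the thousands of subjects in the bundled
table. An exhaustive enumeration oracle validates it for N ≤ 50, and a
simulation check confirms the expected conservativeness of exact tests
(rejection rate ≤ nominal under the null).

`allelicTest()` collapses genotypes to allele counts and applies Pearson
χ² without Yates correction, consistent with the asymptotic framework of
the trend tests; it demands integer tables, since allele counting has no
meaning for expected fractional cells.

## Design choices that were genuinely open

- **S4 with derived margins.** The containers are S4 classes with
  validity methods; margins are computed, never stored, making the
  margin invariants structural rather than tested-for.
- **Error versus NA.** Interactive calls fail loudly on degenerate
  tables; the simulation engine converts the same conditions to counted
  non-rejections. Two consumers, two correct behaviours.
- **Paired comparison.** `powerComparison()` exists because the
  scientific question is a difference of powers, and the shared-replicate
  design with a paired standard error is the efficient estimator of it.
- **Fixtures.** Only tables whose counts are printed as text in the
  source study ship as fixtures (currently rs2398162). Counts that exist
  only inside figure panels are not transcribed.

## Limitations

Single diallelic marker only; no covariate adjustment, stratification,
exact CA test, MAX-type robust statistics, or departures from
Hardy-Weinberg in the population model. The χ²(1) reference for T_JT is
asymptotic with no finite-sample correction. Power curves are emitted as
tidy tables; plotting is left to the user.
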