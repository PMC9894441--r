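# genotrend

Trend tests for case-control genetic association at a diallelic marker,
and the machinery to compare their power across modes of inheritance.

## The problem

A case-control genetic association study at a diallelic locus produces a
2×3 contingency table: case counts (r₀, r₁, r₂) and control counts
(s₀, s₁, s₂) over the genotypes (aa, Aa, AA), ordered by copies of the
minor allele A. The alternative of interest is ordered — the probability
of being a case does not decrease with the number of A alleles — and two
classical 1-d.f. trend tests address it:

- **Cochran-Armitage (CA)**: assigns scores (x₀, x₁, x₂) to the
  genotypes, with x₀ ≤ x₁ ≤ x₂ and x₀ < x₂, and tests for a linear
  trend:

  T_CA = N (N Σ rᵢxᵢ − R Σ nᵢxᵢ)² / { R S [N Σ nᵢxᵢ² − (Σ nᵢxᵢ)²] },

  where nᵢ = rᵢ + sᵢ, R = Σrᵢ, S = Σsᵢ, N = R + S. The score vector
  encodes a genetic-model assumption; the usual default is the additive
  (0, 0.5, 1).

- **Jonckheere-Terpstra (JT)**: rank-based and score-free. With U the
  Mann-Whitney aggregate over all pairs of subjects from distinct
  genotype groups (1 / 0.5 / 0 for phenotype below / tied / above),

  T_JT = [U − E(U)]² / Var(U),

  with E(U) = (N² − Σnᵢ²)/4 and the tie-corrected variance
  Var(U) = A/72 + B/[36N(N−1)(N−2)] + C/[8N(N−1)] (A, B, C correct for
  the genotype-group and phenotype-group ties). Both statistics are
  referred to χ²(1).

Which test is more powerful depends on the unknown true mode of
inheritance. The package provides a genetic-model parameterization to
study exactly that: genotype relative risks λ₁ = 1 + λ cos θ,
λ₂ = 1 + λ sin θ with θ ∈ [π/4, π/2] sweeping dominant → additive →
recessive, penetrances fixed by the prevalence K under Hardy-Weinberg
genotype frequencies, trinomial Monte-Carlo power simulation, and a
deterministic comparison ΔT = (T_JT − T_CA)/T_CA × 100% evaluated on
tables of *expected* cell counts.

Supporting tools: the exact Hardy-Weinberg equilibrium test (log-space,
safe for thousands of subjects) and the allelic (allele-count) χ² test.

## Worked example

The bundled `rs2398162` table (hypertension; 1940 cases, 2923 controls):

```r
library(genotrend)
tb <- exampleTable("rs2398162")
tb
#> GenotypeTable 'rs2398162' (integer counts)
#>            aa   Aa  AA total
#> cases    1205  624 111  1940
#> controls 1608 1121 194  2923
#> total    2813 1745 305  4863

jtTrendTest(tb)
#> Jonckheere-Terpstra trend test
#>   statistic = 22.82 on 1 d.f., p-value = 1.779e-06
#>   U = 2.94978e+06, E(U) = 3.14944e+06, Var(U) = 1.74685e+09

caTrendTest(tb)                # additive scores (0, 0.5, 1)
#> Cochran-Armitage trend test
#>   statistic = 19.97 on 1 d.f., p-value = 7.848e-06
#>   scores = (0, 0.5, 1)
```

The rank-based statistic (22.82) exceeds the additive-score statistic
(19.97): at this variant the minor allele acts near-dominantly, and a
test that does not assume the additive dose-response extracts more of
the signal.

The same ordering appears analytically. On the table of expected counts
under a dominant model with prevalence 0.1, MAF 0.05, λ = 1, N = 200:

```r
m <- geneticModel(prevalence = 0.1, maf = 0.05, lambda = 1, model = "dominant")
deltaT(m, N = 200)
#>     N prevalence  maf lambda thetaPrime      tJT      tCA   deltaT
#> 1 200        0.1 0.05      1       0.25 1.923348 1.882841 2.151383
```

ΔT = +2.15%: the JT statistic is theoretically ahead under the dominant
model. `deltaTGrid()` sweeps N ∈ {200, 500, 1000} × MAF ∈ {0.05, 0.1,
0.2, 0.3} × {dominant, additive, recessive}; ΔT is positive for every
dominant cell, within ±2% for every additive cell, and strongly negative
(down to −69%) for every recessive cell.

Monte-Carlo power tells the same story with sampling noise attached:

```r
m <- geneticModel(0.1, 0.3, lambda = 1, model = "dominant")
powerComparison(m, N = 1000, testA = "jt", testB = "ca_additive",
                reps = 2000, seed = 903)
#>   testA       testB powerA powerB   diff      seDiff degenerate reps alpha seed
#> 1    jt ca_additive  0.994 0.9895 0.0045 0.001496995          0 2000  0.05  903
```

A command-line front end wraps all of this:

```sh
$(Rscript -e 'cat(system.file("exec", "genotrend", package = "genotrend"))') \
    test --fixture rs2398162 --method jt
genotrend compare-theoretical --format text
genotrend simulate-power --maf 0.3 --N 1000 --grid 0.25,0.35,0.5 --seed 7
```

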