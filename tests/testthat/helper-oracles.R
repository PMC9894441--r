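# Independent brute-force oracles used across the suite. These
# deliberately work at the individual level (or by exhaustive
# enumeration) so they share no algebra with the package's closed forms.

# Random integer genotype table with N in [nmin, nmax], at least two
# non-empty genotype columns and at least one case and one control.
randomIntegerTable <- function(nmax = 30, nmin = 6) {
  repeat {
    N <- sample(nmin:nmax, 1)
    cells <- as.vector(stats::rmultinom(1, N, prob = runif(6, 0.2, 1)))
    r <- cells[1:3]; s <- cells[4:6]
    n <- r + s
    if (sum(n > 0) >= 2 && sum(r) >= 1 && sum(s) >= 1)
      return(genotypeTable(r, s, label = "random"))
  }
}

# Individual-level Mann-Whitney aggregate: materializes one row per
# subject and evaluates the pairwise score over every ordered pair of
# subjects from distinct genotype groups (1 / 0.5 / 0 for phenotype
# below / tied / above, control = 0 < case = 1).
bruteForceUCounts <- function(r, s) {
  g <- rep(rep(0:2, 2), times = c(r, s))
  y <- rep(rep(c(1, 0), each = 3), times = c(r, s))
  score <- outer(y, y, function(a, b) (a < b) + 0.5 * (a == b))
  sum(score[outer(g, g, "<")])
}

bruteForceU <- function(tb) {
  bruteForceUCounts(unname(caseCounts(tb)), unname(controlCounts(tb)))
}

# Exact permutation-null mean and variance of U for given margins
# (n0, n1, n2) and R cases: enumerate every split of the case labels
# across genotype groups, weighted by the number of underlying label
# permutations realizing it. uFun(r, s) supplies the U value of a split.
permutationMomentsCounts <- function(n, R, uFun = bruteForceUCounts) {
  splits <- expand.grid(a0 = 0:n[1], a1 = 0:n[2], a2 = 0:n[3])
  splits <- splits[rowSums(splits) == R, , drop = FALSE]
  w <- choose(n[1], splits$a0) * choose(n[2], splits$a1) *
    choose(n[3], splits$a2)
  u <- vapply(seq_len(nrow(splits)), function(i) {
    a <- as.numeric(splits[i, ])
    uFun(a, n - a)
  }, numeric(1))
  w <- w / sum(w)
  m <- sum(w * u)
  list(EU = m, VarU = sum(w * (u - m)^2))
}

permutationMomentsU <- function(tb, uFun = bruteForceUCounts) {
  permutationMomentsCounts(unname(genotypeTotals(tb)), nCases(tb),
                           uFun = uFun)
}

# All genotype-margin configurations (n0, n1, n2) with total N. The JT
# null moments depend on the table only through these margins and R, so
# enumerating (margins x R) covers every table of size N.
allMarginsOfSize <- function(N) {
  g <- expand.grid(n0 = 0:N, n1 = 0:N)
  g <- g[rowSums(g) <= N, , drop = FALSE]
  g$n2 <- N - g$n0 - g$n1
  g
}

# Exact HWE p-value by explicit enumeration of genotype configurations
# with the observed allele counts: a configuration (m0, h, m2) is
# realized by N! / (m0! h! m2!) * 2^h equally likely arrangements of
# the 2N chromosomes.
hweEnumerationP <- function(n0, n1, n2) {
  N <- n0 + n1 + n2
  nA <- n1 + 2 * n2
  hs <- seq.int(nA %% 2, min(nA, 2 * N - nA), by = 2)
  if (length(hs) <= 1) return(1)
  w <- vapply(hs, function(h) {
    m2 <- (nA - h) / 2
    m0 <- N - h - m2
    factorial(N) / (factorial(m0) * factorial(h) * factorial(m2)) * 2^h
  }, numeric(1))
  p <- w / sum(w)
  obs <- p[match(n1, hs)]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# Direct Pearson chi-square on a 2x2 matrix, from first principles.
pearson2x2 <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

rs2398162 <- function() {
  genotypeTable(c(1205, 624, 111), c(1608, 1121, 194), label = "rs2398162")
}
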