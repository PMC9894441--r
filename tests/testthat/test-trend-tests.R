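test_that("chi-squared(1) upper tail matches the erfc identity", {
  expect_equal(chisq1UpperTail(0), 1)
  expect_equal(chisq1UpperTail(3.841459), 0.05, tolerance = 1e-6)
  # P(X >= x) = erfc(sqrt(x/2)) = 2 * pnorm(-sqrt(x))
  for (x in c(0.1, 1, 3.84, 10, 19.97, 40))
    expect_equal(chisq1UpperTail(x), 2 * pnorm(-sqrt(x)), tolerance = 1e-12)
  expect_true(all(diff(chisq1UpperTail(seq(0, 30, 0.5))) <= 0))
  expect_error(chisq1UpperTail(-1), "non-negative")
})

test_that("CA trend test reproduces the published rs2398162 analysis", {
  res <- caTrendTest(rs2398162(), caScores("additive"))
  expect_equal(statistic(res), 19.97, tolerance = 0.005 / 19.97)
  expect_equal(pValue(res), 7.9e-6, tolerance = 0.01)
})

test_that("CA statistic is zero under exact case/control proportionality", {
  n <- c(40, 30, 10)
  tb <- genotypeTable(0.3 * n, 0.7 * n)
  expect_equal(statistic(caTrendTest(tb)), 0, tolerance = 1e-20)
  expect_equal(pValue(caTrendTest(tb)), 1)
  expect_equal(statistic(jtTrendTest(tb)), 0, tolerance = 1e-20)
  expect_equal(jtUStatistic(tb), jtNullMoments(tb)$EU)
})

test_that("CA statistic is invariant to positive affine score changes", {
  set.seed(401)
  for (i in 1:20) {
    tb <- randomIntegerTable(60)
    s1 <- statistic(caTrendTest(tb, c(0, 0.5, 1)))
    s2 <- statistic(caTrendTest(tb, c(0, 1, 2)))
    s3 <- statistic(caTrendTest(tb, 3 + 1.7 * c(0, 0.5, 1)))
    expect_equal(s2, s1, tolerance = 1e-10)
    expect_equal(s3, s1, tolerance = 1e-10)
  }
})

test_that("score vectors violating the ordering constraints are rejected", {
  tb <- rs2398162()
  expect_error(caTrendTest(tb, c(1, 0.5, 0)), "non-decreasing")
  expect_error(caTrendTest(tb, c(0, 0, 0)), "x0 < x2")
  expect_error(caTrendTest(tb, c(0, 0.5)), "x0, x1, x2")
})

test_that("degenerate tables raise informative errors", {
  # all weight on one genotype column: no score contrast
  one <- genotypeTable(c(5, 0, 0), c(7, 0, 0))
  expect_error(caTrendTest(one), "degenerate")
  expect_error(jtNullMoments(one), "degenerate")
  # single-phenotype tables: no case/control contrast
  cases_only <- genotypeTable(c(2, 3, 1), c(0, 0, 0))
  expect_error(caTrendTest(cases_only), "no contrast")
  expect_error(jtNullMoments(genotypeTable(c(1, 1, 0), c(0, 0, 0))),
               "too small|degenerate")
  expect_error(jtNullMoments(genotypeTable(c(2, 1, 0), c(0, 0, 0))),
               "degenerate")
  expect_error(jtNullMoments(genotypeTable(c(1, 0, 0), c(1, 0, 0))),
               "too small|degenerate")
})

test_that("closed-form U equals the individual-level triple sum", {
  tb <- genotypeTable(c(1, 0, 1), c(1, 1, 0))
  expect_equal(jtUStatistic(tb), 3.0)  # hand-computed pairwise sum
  expect_equal(bruteForceU(tb), 3.0)
  set.seed(402)
  for (i in 1:25) {
    tb <- randomIntegerTable(30)
    expect_equal(jtUStatistic(tb), bruteForceU(tb), tolerance = 1e-12)
  }
})

test_that("E(U) formula agrees with the pairwise-count identity", {
  set.seed(403)
  for (i in 1:20) {
    tb <- randomIntegerTable(80)
    n <- unname(genotypeTotals(tb))
    pairSum <- (n[1] * n[2] + n[1] * n[3] + n[2] * n[3]) / 2
    expect_equal(jtNullMoments(tb)$EU, pairSum)
  }
})

test_that("null moments match the exhaustive permutation distribution", {
  tb <- genotypeTable(c(2, 1, 1), c(1, 2, 1))
  m <- jtNullMoments(tb)
  o <- permutationMomentsU(tb, uFun = bruteForceUCounts)
  expect_equal(m$EU, o$EU, tolerance = 1e-12)
  expect_equal(m$VarU, o$VarU, tolerance = 1e-9)
  set.seed(404)
  for (i in 1:10) {
    tb <- randomIntegerTable(nmax = 10, nmin = 4)
    m <- jtNullMoments(tb)
    o <- permutationMomentsU(tb, uFun = bruteForceUCounts)
    expect_equal(m$EU, o$EU, tolerance = 1e-12)
    expect_equal(m$VarU, o$VarU, tolerance = 1e-9)
  }
})

test_that("JT test reproduces the published rs2398162 analysis", {
  res <- jtTrendTest(rs2398162())
  expect_equal(statistic(res), 22.82, tolerance = 0.005 / 22.82)
  expect_equal(pValue(res), 1.8e-6, tolerance = 0.02)
})

test_that("both statistics are invariant to label swap and column reversal", {
  set.seed(405)
  for (i in 1:15) {
    tb <- randomIntegerTable(50)
    r <- unname(caseCounts(tb)); s <- unname(controlCounts(tb))
    swapped <- genotypeTable(s, r)
    reversed <- genotypeTable(rev(r), rev(s))
    for (f in list(function(t) statistic(jtTrendTest(t)),
                   function(t) statistic(caTrendTest(t)))) {
      expect_equal(f(swapped), f(tb), tolerance = 1e-10)
      expect_equal(f(reversed), f(tb), tolerance = 1e-10)
    }
  }
})

test_that("statistics respond continuously to small cell perturbations", {
  tb <- rs2398162()
  r <- unname(caseCounts(tb)); s <- unname(controlCounts(tb))
  eps <- 1e-6
  for (f in list(function(t) statistic(jtTrendTest(t)),
                 function(t) statistic(caTrendTest(t)))) {
    base <- f(tb)
    bump <- f(genotypeTable(r + c(eps, 0, 0), s, fractional = TRUE))
    expect_lt(abs(bump - base), 1e-3)
    expect_false(identical(bump, base))
  }
})

test_that("null JT statistics follow chi-squared(1)", {
  set.seed(406)
  m <- geneticModel(0.1, 0.2, lambda = 0, model = "additive")
  probs <- cellProbabilities(m)
  stats <- replicate(200, {
    tb <- simulateGenotypeTable(probs, R = 250, S = 250)
    statistic(jtTrendTest(tb))
  })
  ks <- suppressWarnings(ks.test(stats, pchisq, df = 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("JT output flags small genotype groups as an asymptotic caveat", {
  res <- jtTrendTest(genotypeTable(c(10, 8, 1), c(12, 9, 2)))
  expect_match(res@notes, "asymptotic")
})
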