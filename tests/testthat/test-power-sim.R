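test_that("trinomial draws respect margins, moments and determinism", {
  probs <- list(tau = c(0.5, 0.3, 0.2), upsilon = c(0.6, 0.3, 0.1))
  set.seed(701)
  draws <- replicate(2000, {
    tb <- simulateGenotypeTable(probs, R = 500, S = 400)
    stopifnot(nCases(tb) == 500, nControls(tb) == 400)
    unname(caseCounts(tb))[1]
  })
  se <- sqrt(500 * 0.5 * 0.5) / sqrt(2000)
  expect_lt(abs(mean(draws) - 250), 3 * se)
  # fixed seed gives identical tables
  m <- geneticModel(0.1, 0.2, 1, model = "dominant")
  set.seed(77); t1 <- simulateGenotypeTable(m, 100, 100)
  set.seed(77); t2 <- simulateGenotypeTable(m, 100, 100)
  expect_identical(caseCounts(t1), caseCounts(t2))
  expect_identical(controlCounts(t1), controlCounts(t2))
})

test_that("vectorized simulation kernels agree with the per-table tests", {
  set.seed(702)
  tabs <- replicate(30, randomIntegerTable(120, nmin = 20), simplify = FALSE)
  rmat <- vapply(tabs, function(t) unname(caseCounts(t)), numeric(3))
  smat <- vapply(tabs, function(t) unname(controlCounts(t)), numeric(3))
  jtRef <- vapply(tabs, function(t) statistic(jtTrendTest(t)), numeric(1))
  caRef <- vapply(tabs, function(t) statistic(caTrendTest(t)), numeric(1))
  alRef <- vapply(tabs, function(t) statistic(allelicTest(t)), numeric(1))
  expect_equal(genotrend:::jtStatVec(rmat, smat), jtRef, tolerance = 1e-10)
  expect_equal(genotrend:::caStatVec(rmat, smat, c(0, 0.5, 1)), caRef,
               tolerance = 1e-10)
  expect_equal(genotrend:::allelicStatVec(rmat, smat), alRef,
               tolerance = 1e-10)
})

test_that("vectorized kernels mark degenerate tables NA instead of failing", {
  rmat <- cbind(c(5, 0, 0), c(3, 2, 1))
  smat <- cbind(c(7, 0, 0), c(4, 1, 1))
  jt <- genotrend:::jtStatVec(rmat, smat)
  ca <- genotrend:::caStatVec(rmat, smat, c(0, 0.5, 1))
  expect_true(is.na(jt[1]) && is.na(ca[1]))
  expect_false(is.na(jt[2]) || is.na(ca[2]))
})

test_that("empirical power runs are reproducible and well-formed", {
  m <- geneticModel(0.1, 0.2, 1, model = "dominant")
  p1 <- empiricalPower(m, N = 200, reps = 400, seed = 11,
                       tests = c("jt", "ca_additive", "allelic"))
  p2 <- empiricalPower(m, N = 200, reps = 400, seed = 11,
                       tests = c("jt", "ca_additive", "allelic"))
  expect_identical(p1, p2)
  expect_true(all(p1$power >= 0 & p1$power <= 1))
  expect_equal(p1$se, sqrt(p1$power * (1 - p1$power) / 400))
})

test_that("power increases with effect distance at fixed model", {
  half <- empiricalPower(geneticModel(0.1, 0.3, 0.5, model = "additive"),
                         N = 500, reps = 1000, seed = 12)
  full <- empiricalPower(geneticModel(0.1, 0.3, 1, model = "additive"),
                         N = 500, reps = 1000, seed = 12)
  comb <- sqrt(half$se^2 + full$se^2)
  expect_true(all(full$power >= half$power - 2 * comb))
})

test_that("power curve output is grid-shaped, bounded and bit-stable", {
  grid <- c(0.25, 0.4, 0.5)
  out1 <- withr::local_tempfile(fileext = ".tsv")
  out2 <- withr::local_tempfile(fileext = ".tsv")
  c1 <- powerCurve(0.1, 0.2, 1, thetaPrimeGrid = grid, N = 200,
                   reps = 300, seed = 5, out = out1)
  c2 <- powerCurve(0.1, 0.2, 1, thetaPrimeGrid = grid, N = 200,
                   reps = 300, seed = 5, out = out2)
  expect_identical(readLines(out1), readLines(out2))
  expect_equal(unique(c1$thetaPrime), grid)
  expect_equal(nrow(c1), length(grid) * 2)
  expect_error(powerCurve(0.1, 0.2, 1, thetaPrimeGrid = c(0.2, 0.5),
                          N = 200, reps = 10), "0.25, 0.5")
})

test_that("null power curve is flat near the nominal level", {
  c0 <- powerCurve(0.1, 0.2, 0, thetaPrimeGrid = c(0.25, 0.375, 0.5),
                   N = 500, reps = 1000, seed = 13)
  # 4 Monte-Carlo SEs around alpha = 0.05 at 1000 reps
  expect_true(all(abs(c0$power - 0.05) < 4 * sqrt(0.05 * 0.95 / 1000)))
})

test_that("degenerate replicates are counted, not dropped", {
  # tiny N and rare allele: empty-column tables are common
  m <- geneticModel(0.1, 0.02, 1, model = "recessive")
  p <- empiricalPower(m, N = 20, reps = 500, seed = 14,
                      tests = c("jt", "ca_additive"))
  expect_true(all(p$degenerate > 0))
  expect_true(all(p$power <= 1 - p$degenerate / p$reps + 1e-12))
})

test_that("paired power comparison is consistent with marginal powers", {
  m <- geneticModel(0.1, 0.3, 1, model = "dominant")
  cmp <- powerComparison(m, N = 500, reps = 1000, seed = 15)
  expect_equal(cmp$diff, cmp$powerA - cmp$powerB, tolerance = 1e-12)
  # same seed, same draws: marginal powers equal the unpaired runs
  p <- empiricalPower(m, N = 500, reps = 1000, seed = 15,
                      tests = c("jt", "ca_additive"))
  expect_equal(cmp$powerA, p$power[p$test == "jt"])
  expect_equal(cmp$powerB, p$power[p$test == "ca_additive"])
  # under the null the paired difference is centred at zero
  m0 <- geneticModel(0.1, 0.3, 0, model = "dominant")
  c0 <- powerComparison(m0, N = 500, reps = 2000, seed = 16)
  expect_lt(abs(c0$diff), 4 * c0$seDiff + 1e-9)
})
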