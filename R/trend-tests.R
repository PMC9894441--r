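#' Genotype score presets for the Cochran-Armitage test
#'
#' Scores encode the assumed mode of inheritance of the minor allele:
#' additive (0, 0.5, 1), dominant (0, 1, 1), recessive (0, 0, 1). The
#' additive preset is the usual default because of its robustness across
#' modes of inheritance.
#'
#' @param model one of `"additive"`, `"dominant"`, `"recessive"`.
#' @return numeric(3) score vector (x0, x1, x2).
#' @export
caScores <- function(model = c("additive", "dominant", "recessive")) {
  switch(match.arg(model),
         additive  = c(0, 0.5, 1),
         dominant  = c(0, 1, 1),
         recessive = c(0, 0, 1))
}

validateScores <- function(x) {
  if (!is.numeric(x) || length(x) != 3L || any(!is.finite(x)))
    stop("scores must be a numeric vector (x0, x1, x2)")
  if (x[1L] > x[2L] || x[2L] > x[3L])
    stop("scores must be non-decreasing: x0 <= x1 <= x2")
  if (x[1L] >= x[3L])
    stop("scores must satisfy x0 < x2")
  invisible(x)
}

newResult <- function(statistic, name, notes = "") {
  new("AssocTestResult", statistic = statistic, df = 1,
      pValue = chisq1UpperTail(statistic), testName = name, notes = notes)
}

#' Upper tail of the chi-squared distribution with 1 d.f.
#'
#' `P(X >= x)` for `X ~ chi-squared(1)`; the reference distribution for
#' every statistic in this package.
#'
#' @param x non-negative statistic value(s).
#' @return Upper-tail probabilities in [0, 1].
#' @export
chisq1UpperTail <- function(x) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("chisq1UpperTail is defined for non-negative finite x only")
  stats::pchisq(x, df = 1, lower.tail = FALSE)
}

#' Cochran-Armitage trend test
#'
#' Tests for a linear trend in case proportions across the ordered
#' genotypes (aa, Aa, AA) using a preassigned score vector. With case
#' counts r_i, totals n_i, R cases, S controls and N subjects, the
#' statistic is
#' \deqn{T_{CA} = \frac{N\,(N \sum r_i x_i - R \sum n_i x_i)^2}
#'   {R\,S\,[N \sum n_i x_i^2 - (\sum n_i x_i)^2]},}
#' referred to chi-squared with 1 d.f. The statistic is invariant to
#' positive affine transformation of the scores, so (0, 0.5, 1) and
#' (0, 1, 2) give identical results. Fractional tables (expected counts)
#' are accepted.
#'
#' @param x a [GenotypeTable-class].
#' @param scores numeric(3) with x0 <= x1 <= x2 and x0 < x2; the default
#'   is the additive preset (0, 0.5, 1). See [caScores()].
#' @return An [AssocTestResult-class].
#' @examples
#' tb <- exampleTable("rs2398162")
#' caTrendTest(tb)                       # T = 19.97, p = 7.9e-06
#' caTrendTest(tb, caScores("dominant"))
#' @export
caTrendTest <- function(x, scores = caScores("additive")) {
  stopifnot(is(x, "GenotypeTable"))
  validateScores(scores)
  r <- x@cases; s <- x@controls
  n <- r + s; R <- sum(r); S <- sum(s); N <- R + S
  if (R <= 0 || S <= 0)
    stop("no contrast: the table needs both cases (R > 0) and controls (S > 0)")
  den <- N * sum(n * scores^2) - sum(scores * n)^2
  if (den <= 1e-12 * N^2 * max(scores^2, 1))
    stop("degenerate table: all weight on a single score value, ",
         "the trend variance is zero")
  stat <- N * (N * sum(r * scores) - R * sum(n * scores))^2 / (R * S * den)
  newResult(stat, "Cochran-Armitage trend test",
            notes = paste0("scores = (", paste(scores, collapse = ", "), ")"))
}

#' Mann-Whitney aggregate U for the Jonckheere-Terpstra test
#'
#' U is defined over all pairs of individuals taken from distinct genotype
#' groups i < i', scoring 1 when the first individual's phenotype is below
#' the second's, 0.5 on a tie and 0 otherwise (controls = 0 < cases = 1).
#' With only two phenotype values the pairwise scores aggregate in closed
#' form over the counts: each ordered group pair contributes
#' `s_i * r_k + 0.5 * (r_i * r_k + s_i * s_k)`. No individual-level data
#' are ever materialized, so the computation is O(1) in N.
#'
#' @param x a [GenotypeTable-class].
#' @return The value of U, in `[0, sum over pairs of n_i * n_k]`.
#' @export
jtUStatistic <- function(x) {
  stopifnot(is(x, "GenotypeTable"))
  r <- x@cases; s <- x@controls
  u <- 0
  for (i in 1:2) for (k in (i + 1L):3) {
    u <- u + s[i] * r[k] + 0.5 * (r[i] * r[k] + s[i] * s[k])
  }
  u
}

#' Null moments of U with tie correction
#'
#' Mean and variance of the Jonckheere-Terpstra U under the null
#' permutation distribution of the binary phenotype over the fixed
#' genotype margins. The mean is `E(U) = (N^2 - sum n_i^2) / 4` and the
#' variance carries the tie correction for the genotype groups (sizes
#' n_i) and the two phenotype groups (sizes R and S):
#' \deqn{Var(U) = \frac{A}{72} + \frac{B}{36\,N(N-1)(N-2)}
#'   + \frac{C}{8\,N(N-1)}}
#' with
#' `A = N(N-1)(2N+5) - sum n_i(n_i-1)(2n_i+5) - S(S-1)(2S+5) - R(R-1)(2R+5)`,
#' `B = sum n_i(n_i-1)(n_i-2) * [S(S-1)(S-2) + R(R-1)(R-2)]`, and
#' `C = sum n_i(n_i-1) * [S(S-1) + R(R-1)]`. These closed forms equal the
#' exact mean and variance of U over all phenotype-label permutations
#' (verified exhaustively in the test suite).
#'
#' @param x a [GenotypeTable-class] with N >= 3.
#' @return A list with components `EU`, `VarU` and the variance pieces
#'   `A`, `B`, `C`.
#' @export
jtNullMoments <- function(x) {
  stopifnot(is(x, "GenotypeTable"))
  r <- x@cases; s <- x@controls
  n <- r + s; R <- sum(r); S <- sum(s); N <- R + S
  if (N < 3)
    stop("table too small: the tie-corrected variance needs N >= 3")
  EU <- (N^2 - sum(n^2)) / 4
  A <- N * (N - 1) * (2 * N + 5) - sum(n * (n - 1) * (2 * n + 5)) -
    S * (S - 1) * (2 * S + 5) - R * (R - 1) * (2 * R + 5)
  B <- sum(n * (n - 1) * (n - 2)) *
    (S * (S - 1) * (S - 2) + R * (R - 1) * (R - 2))
  C <- sum(n * (n - 1)) * (S * (S - 1) + R * (R - 1))
  VarU <- A / 72 + B / (36 * N * (N - 1) * (N - 2)) + C / (8 * N * (N - 1))
  if (VarU <= 1e-12 * max(N^3, 1))
    stop("degenerate table: Var(U) = 0 ",
         "(needs >= 2 non-empty genotype groups and both cases and controls)")
  list(EU = EU, VarU = VarU, A = A, B = B, C = C)
}

#' Jonckheere-Terpstra trend test
#'
#' Rank-based test of the ordered alternative that the case probability
#' is monotone across genotypes (aa, Aa, AA), requiring no genotype
#' scores and hence no assumed mode of inheritance. The statistic is
#' \deqn{T_{JT} = \frac{[U - E(U)]^2}{Var(U)},}
#' with U from [jtUStatistic()] and the tie-corrected null moments from
#' [jtNullMoments()]; for large N with no genotype group too small it is
#' referred to chi-squared with 1 d.f. Fractional tables (expected
#' counts) are accepted, which is what makes theoretical comparison of
#' the two trend statistics possible.
#'
#' @param x a [GenotypeTable-class].
#' @return An [AssocTestResult-class]; `notes` records U, E(U) and Var(U).
#' @examples
#' tb <- exampleTable("rs2398162")
#' jtTrendTest(tb)   # T = 22.82, p = 1.8e-06
#' @export
jtTrendTest <- function(x) {
  stopifnot(is(x, "GenotypeTable"))
  U <- jtUStatistic(x)
  m <- jtNullMoments(x)
  stat <- (U - m$EU)^2 / m$VarU
  small <- min(genotypeTotals(x))
  notes <- sprintf("U = %.6g, E(U) = %.6g, Var(U) = %.6g", U, m$EU, m$VarU)
  if (small < 5)
    notes <- paste0(notes, "; smallest genotype group has ", format(small),
                    " subjects: the chi-squared reference is asymptotic ",
                    "and may be inaccurate")
  newResult(stat, "Jonckheere-Terpstra trend test", notes = notes)
}

setMethod("show", "AssocTestResult", function(object) {
  cat(object@testName, "\n")
  cat(sprintf("  statistic = %.4g on %d d.f., p-value = %.4g\n",
              object@statistic, as.integer(object@df), object@pValue))
  if (nzchar(object@notes)) cat("  ", object@notes, "\n", sep = "")
  invisible(NULL)
})

#' Accessors for AssocTestResult objects
#'
#' @param x an [AssocTestResult-class].
#' @return The statistic value, p-value, or test name.
#' @name assocTestResult-accessors
#' @aliases statistic pValue testName
NULL

#' @rdname assocTestResult-accessors
#' @export
setMethod("statistic", "AssocTestResult", function(x) x@statistic)

#' @rdname assocTestResult-accessors
#' @export
setMethod("pValue", "AssocTestResult", function(x) x@pValue)

#' @rdname assocTestResult-accessors
#' @export
setMethod("testName", "AssocTestResult", function(x) x@testName)
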