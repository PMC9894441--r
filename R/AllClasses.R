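#' @import methods
NULL

#' GenotypeTable: a 2x3 case-control genotype count table
#'
#' Container for genotype counts at a diallelic marker in a case-control
#' study. Columns are ordered by copies of the minor allele A:
#' (aa, Aa, AA). Margins (genotype totals, case total R, control total S,
#' grand total N) are always derived from the cells, never stored.
#'
#' Counts are usually integers (observed data), but fractional cells are a
#' first-class mode: tables of expected cell values under a genetic model
#' are non-integer by construction, and every test in this package accepts
#' them. The `fractional` slot records which mode a table is in.
#'
#' @slot cases numeric(3), case counts (r0, r1, r2) for (aa, Aa, AA).
#' @slot controls numeric(3), control counts (s0, s1, s2).
#' @slot label character(1), free-text identifier (e.g. a variant ID).
#' @slot fractional logical(1), TRUE when any cell is non-integer.
#'
#' @seealso [genotypeTable()] for the user-facing constructor,
#'   [caseCounts()], [controlCounts()], [genotypeTotals()], [nTotal()].
#' @export
setClass("GenotypeTable",
  representation(
    cases = "numeric",
    controls = "numeric",
    label = "character",
    fractional = "logical"
  )
)

setValidity("GenotypeTable", function(object) {
  msgs <- character()
  if (length(object@cases) != 3L || length(object@controls) != 3L)
    msgs <- c(msgs, "cases and controls must each have length 3 (aa, Aa, AA)")
  cells <- c(object@cases, object@controls)
  if (any(!is.finite(cells)))
    msgs <- c(msgs, "all cell counts must be finite")
  else if (any(cells < 0))
    msgs <- c(msgs, "all cell counts must be non-negative")
  else if (sum(cells) <= 0)
    msgs <- c(msgs, "total sample size N must be > 0")
  if (length(object@fractional) != 1L || is.na(object@fractional))
    msgs <- c(msgs, "fractional flag must be TRUE or FALSE")
  else if (!object@fractional && length(msgs) == 0L &&
           any(abs(cells - round(cells)) > 1e-9))
    msgs <- c(msgs, "non-integer cells in a table not flagged fractional")
  if (length(msgs)) msgs else TRUE
})

#' GeneticModel: a single-locus disease model on the dominant-recessive arc
#'
#' Parameterizes a diallelic disease model by prevalence K, minor allele
#' frequency q, effect distance lambda, and angle theta. Genotype relative
#' risks are lambda1 = 1 + lambda*cos(theta), lambda2 = 1 + lambda*sin(theta),
#' so theta = pi/4, arctan 2, pi/2 give the dominant (lambda1 = lambda2),
#' additive (lambda1 = (1+lambda2)/2) and recessive (lambda1 = 1) models,
#' and lambda = 0 is the null regardless of theta. Penetrances and the
#' case/control genotype cell probabilities are derived, not stored
#' (see [cellProbabilities()]).
#'
#' @slot prevalence numeric(1), disease prevalence K in (0,1).
#' @slot maf numeric(1), minor allele frequency q in (0,1).
#' @slot lambda numeric(1), effect distance lambda >= 0.
#' @slot theta numeric(1), model angle in radians, in [pi/4, pi/2].
#'
#' @seealso [geneticModel()], [relativeRisks()], [cellProbabilities()].
#' @export
setClass("GeneticModel",
  representation(
    prevalence = "numeric",
    maf = "numeric",
    lambda = "numeric",
    theta = "numeric"
  )
)

setValidity("GeneticModel", function(object) {
  msgs <- character()
  chk1 <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x)) paste0(nm, " must be a single finite number") else NULL
  }
  msgs <- c(msgs, chk1(object@prevalence, "prevalence"),
                  chk1(object@maf, "maf"),
                  chk1(object@lambda, "lambda"),
                  chk1(object@theta, "theta"))
  if (length(msgs) == 0L) {
    if (object@prevalence <= 0 || object@prevalence >= 1)
      msgs <- c(msgs, "prevalence must lie in (0, 1)")
    if (object@maf <= 0 || object@maf >= 1)
      msgs <- c(msgs, "maf must lie in (0, 1)")
    if (object@lambda < 0)
      msgs <- c(msgs, "lambda must be >= 0")
    if (object@theta < pi / 4 - 1e-12 || object@theta > pi / 2 + 1e-12)
      msgs <- c(msgs, "theta must lie in [pi/4, pi/2]")
  }
  if (length(msgs)) msgs else TRUE
})

#' AssocTestResult: outcome of a one-degree-of-freedom association test
#'
#' Holds a test statistic, its reference degrees of freedom, the upper-tail
#' chi-squared p-value, the test name and free-text notes. All tests in this
#' package are squared statistics referred to chi-squared with 1 d.f., so
#' p-values are two-sided with respect to the direction of trend.
#'
#' @slot statistic numeric(1), non-negative test statistic.
#' @slot df numeric(1), reference degrees of freedom (1 for all tests here).
#' @slot pValue numeric(1), upper-tail chi-squared p-value in [0,1].
#' @slot testName character(1).
#' @slot notes character(1).
#'
#' @seealso [jtTrendTest()], [caTrendTest()], [allelicTest()],
#'   [statistic()], [pValue()].
#' @export
setClass("AssocTestResult",
  representation(
    statistic = "numeric",
    df = "numeric",
    pValue = "numeric",
    testName = "character",
    notes = "character"
  )
)

setValidity("AssocTestResult", function(object) {
  msgs <- character()
  if (length(object@statistic) != 1L || !is.finite(object@statistic) ||
      object@statistic < 0)
    msgs <- c(msgs, "statistic must be a single non-negative finite number")
  if (length(object@df) != 1L || object@df < 1)
    msgs <- c(msgs, "df must be a positive integer")
  if (length(object@pValue) != 1L || is.na(object@pValue) ||
      object@pValue < 0 || object@pValue > 1)
    msgs <- c(msgs, "pValue must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})
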