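#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on genotype counts (n0, n1, n2) = (aa, Aa, AA).
#' Conditional on the observed allele counts nA = n1 + 2 n2 and
#' na = n1 + 2 n0, the number of heterozygotes h under Hardy-Weinberg
#' equilibrium has probability
#' \deqn{P(h \mid n_A, N) \propto \frac{2^h}
#'   {((n_A-h)/2)!\; h!\; ((n_a-h)/2)!},}
#' over the h of the same parity as nA. The p-value sums the
#' probabilities of all configurations no more likely than the observed
#' one (the usual "sum of less-likely outcomes" convention). Probabilities
#' are accumulated in log space so large samples do not overflow the
#' factorials. A marker with a single attainable configuration (e.g.
#' monomorphic) returns 1.
#'
#' @param n0,n1,n2 non-negative integer genotype counts for aa, Aa, AA.
#' @return The exact two-sided p-value in [0, 1].
#' @examples
#' hweExactTest(1205, 624, 111)   # cases of rs2398162
#' @export
hweExactTest <- function(n0, n1, n2) {
  cnt <- c(n0, n1, n2)
  if (length(cnt) != 3L || any(!is.finite(cnt)) || any(cnt < 0))
    stop("genotype counts must be three non-negative numbers")
  if (any(abs(cnt - round(cnt)) > 1e-9))
    stop("exact HWE test is defined for integer genotype counts only")
  cnt <- round(cnt)
  N <- sum(cnt)
  if (N < 1) stop("at least one subject is required")
  nA <- cnt[2L] + 2 * cnt[3L]
  hs <- seq.int(nA %% 2L, min(nA, 2L * N - nA), by = 2L)
  if (length(hs) <= 1L) return(1)
  # log P(h) up to the shared normalizing constant
  lp <- hs * log(2) - lgamma((nA - hs) / 2 + 1) - lgamma(hs + 1) -
    lgamma((2 * N - nA - hs) / 2 + 1)
  lp <- lp - max(lp)
  p <- exp(lp) / sum(exp(lp))
  obs <- p[match(cnt[2L], hs)]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

#' Allelic association test
#'
#' Collapses the 2x3 genotype table into a 2x2 table of allele counts —
#' cases (2 r0 + r1, r1 + 2 r2), controls (2 s0 + s1, s1 + 2 s2) — and
#' applies the Pearson chi-squared test with 1 d.f., without continuity
#' correction. The allele-level view doubles the sample to 2N chromosomes
#' and is not robust to departures from Hardy-Weinberg equilibrium, so it
#' is reported here as a companion to the trend tests rather than a
#' replacement.
#'
#' @param x a [GenotypeTable-class] with integer counts.
#' @return An [AssocTestResult-class].
#' @examples
#' allelicTest(exampleTable("rs2398162"))
#' @export
allelicTest <- function(x) {
  stopifnot(is(x, "GenotypeTable"))
  if (isFractional(x))
    stop("the allelic test is defined for integer genotype counts")
  r <- x@cases; s <- x@controls
  m <- rbind(cases    = c(2 * r[1L] + r[2L], r[2L] + 2 * r[3L]),
             controls = c(2 * s[1L] + s[2L], s[2L] + 2 * s[3L]))
  colnames(m) <- c("a", "A")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("no contrast: a margin of the 2x2 allele-count table is zero")
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  newResult(unname(ht$statistic), "allelic association test",
            notes = sprintf("allele counts cases (%g, %g), controls (%g, %g)",
                            m[1L, 1L], m[1L, 2L], m[2L, 1L], m[2L, 2L]))
}
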