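#' Expected genotype table under a genetic model
#'
#' Builds the fractional table of expected cell values under a balanced
#' design: `E(r_i) = tau_i * N / 2` and `E(s_i) = upsilon_i * N / 2`.
#' Both trend tests accept this fractional table, which lets the two
#' statistics be compared analytically, without Monte-Carlo noise.
#'
#' @param model a [GeneticModel-class].
#' @param N total sample size (cases and controls each contribute N/2
#'   expected subjects).
#' @return A fractional-mode [GenotypeTable-class] with row sums N/2.
#' @examples
#' m <- geneticModel(0.1, 0.2, lambda = 1, model = "dominant")
#' expectedTable(m, N = 1000)
#' @export
expectedTable <- function(model, N) {
  stopifnot(is(model, "GeneticModel"), N > 0)
  probs <- cellProbabilities(model)
  genotypeTable(probs$tau * N / 2, probs$upsilon * N / 2,
                label = sprintf("expected(K=%g, q=%g, lambda=%g, theta'=%.4f, N=%g)",
                                model@prevalence, model@maf, model@lambda,
                                model@theta / pi, N),
                fractional = TRUE)
}

#' Percent difference between the theoretical trend statistics
#'
#' Evaluates the Jonckheere-Terpstra and the additive-score
#' Cochran-Armitage statistics on the expected genotype table of a model
#' (see [expectedTable()]) and returns
#' `deltaT = (T_JT - T_CA) / T_CA * 100`. A positive value indicates the
#' rank-based test extracts more signal from the configuration than the
#' additive-score test, i.e. it is the theoretically more powerful of
#' the two there; negative means the reverse. Requires `lambda > 0`:
#' under the null both statistics are 0 and the ratio is undefined.
#'
#' @param model a [GeneticModel-class] with `lambda > 0`.
#' @param N total sample size of the expected table.
#' @return A data.frame row: `N`, `prevalence`, `maf`, `lambda`,
#'   `thetaPrime`, `tJT`, `tCA`, `deltaT` (in percent).
#' @examples
#' m <- geneticModel(0.1, 0.05, lambda = 1, model = "dominant")
#' deltaT(m, N = 200)   # deltaT about 2.15
#' @export
deltaT <- function(model, N) {
  stopifnot(is(model, "GeneticModel"))
  if (model@lambda <= 0)
    stop("deltaT is undefined at lambda = 0: both statistics vanish ",
         "on the null expected table")
  tb <- expectedTable(model, N)
  tJT <- statistic(jtTrendTest(tb))
  tCA <- statistic(caTrendTest(tb, caScores("additive")))
  if (tCA <= 0)
    stop("deltaT is undefined: the theoretical CA statistic is zero")
  data.frame(N = N, prevalence = model@prevalence, maf = model@maf,
             lambda = model@lambda, thetaPrime = model@theta / pi,
             tJT = tJT, tCA = tCA, deltaT = (tJT - tCA) / tCA * 100)
}

#' Theoretical comparison grid over sample sizes, MAFs and models
#'
#' Computes [deltaT()] for every combination of sample size, minor allele
#' frequency and genetic model. The defaults reproduce the full
#' deterministic comparison grid at prevalence 0.1 and effect distance 1:
#' N in \{200, 500, 1000\} by q in \{0.05, 0.1, 0.2, 0.3\} under the
#' dominant, additive and recessive models.
#'
#' @param N vector of total sample sizes.
#' @param maf vector of minor allele frequencies.
#' @param prevalence disease prevalence K.
#' @param lambda effect distance (> 0).
#' @param models character vector of model presets.
#' @param out optional path for a tidy TSV copy.
#' @return A data.frame, one row per (N, maf, model) combination, with a
#'   `model` column ahead of the [deltaT()] columns.
#' @examples
#' g <- deltaTGrid(N = c(200, 1000), maf = c(0.05, 0.3))
#' format(g$deltaT, digits = 4)
#' @export
deltaTGrid <- function(N = c(200, 500, 1000),
                       maf = c(0.05, 0.1, 0.2, 0.3),
                       prevalence = 0.1, lambda = 1,
                       models = c("dominant", "additive", "recessive"),
                       out = NULL) {
  grid <- expand.grid(model = models, maf = maf, N = N,
                      stringsAsFactors = FALSE)[, 3:1]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    m <- geneticModel(prevalence, grid$maf[i], lambda,
                      model = grid$model[i])
    cbind(model = grid$model[i], deltaT(m, grid$N[i]))
  })
  res <- do.call(rbind, rows)
  if (!is.null(out))
    utils::write.table(res, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  res
}
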