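#' Construct a single-locus genetic disease model
#'
#' Parameterizes the disease model by prevalence K, minor allele frequency
#' q, effect distance lambda and model angle theta. The genotype relative
#' risks are `lambda1 = 1 + lambda * cos(theta)` and
#' `lambda2 = 1 + lambda * sin(theta)`, so the arc theta in [pi/4, pi/2]
#' sweeps from the dominant model (lambda1 = lambda2, theta = pi/4)
#' through the additive model (lambda1 = (1 + lambda2)/2,
#' theta = arctan 2) to the recessive model (lambda1 = 1, theta = pi/2).
#' `lambda = 0` is the null model for any theta. The angle can be given
#' in radians (`theta`), as the fraction `thetaPrime = theta / pi` in
#' [0.25, 0.5], or as a named preset (`model`); exactly one of the three
#' must be supplied.
#'
#' @param prevalence disease prevalence K in (0, 1).
#' @param maf population minor allele frequency q in (0, 1).
#' @param lambda effect distance lambda >= 0.
#' @param theta model angle in radians, in [pi/4, pi/2].
#' @param thetaPrime model angle as theta / pi, in [0.25, 0.5].
#' @param model preset name: `"dominant"` (pi/4), `"additive"`
#'   (arctan 2), or `"recessive"` (pi/2).
#' @return A [GeneticModel-class].
#' @examples
#' geneticModel(prevalence = 0.1, maf = 0.2, lambda = 1, model = "additive")
#' geneticModel(0.1, 0.2, lambda = 1, thetaPrime = 0.3)
#' @export
geneticModel <- function(prevalence, maf, lambda, theta = NULL,
                         thetaPrime = NULL, model = NULL) {
  given <- c(theta = !is.null(theta), thetaPrime = !is.null(thetaPrime),
             model = !is.null(model))
  if (sum(given) != 1L)
    stop("supply exactly one of theta, thetaPrime, model")
  if (!is.null(model)) {
    theta <- switch(match.arg(model, c("dominant", "additive", "recessive")),
                    dominant = pi / 4, additive = atan(2), recessive = pi / 2)
  } else if (!is.null(thetaPrime)) {
    if (thetaPrime < 0.25 - 1e-12 || thetaPrime > 0.5 + 1e-12)
      stop("thetaPrime must lie in [0.25, 0.5]")
    theta <- thetaPrime * pi
  }
  new("GeneticModel", prevalence = prevalence, maf = maf,
      lambda = lambda, theta = theta)
}

#' Accessors for GeneticModel objects
#'
#' @param x a [GeneticModel-class].
#' @return A single numeric parameter value.
#' @name geneticModel-accessors
#' @aliases prevalence modelTheta effectDistance
NULL

#' @rdname geneticModel-accessors
#' @export
setMethod("prevalence", "GeneticModel", function(x) x@prevalence)

#' @rdname geneticModel-accessors
#' @export
setMethod("minorAlleleFrequency", "GeneticModel", function(x, ...) x@maf)

#' @rdname geneticModel-accessors
#' @export
setMethod("modelTheta", "GeneticModel", function(x) x@theta)

#' @rdname geneticModel-accessors
#' @export
setMethod("effectDistance", "GeneticModel", function(x) x@lambda)

#' Genotype relative risks of a model
#'
#' `lambda1 = 1 + lambda cos(theta)` and `lambda2 = 1 + lambda sin(theta)`,
#' the penetrance ratios f1/f0 and f2/f0 for the heterozygote and the
#' minor-allele homozygote. Over theta in [pi/4, pi/2] with lambda >= 0
#' both are >= 1, matching the ordered alternative. Also callable on a
#' pair `(lambda, theta)` directly.
#'
#' @param x a [GeneticModel-class], or a single lambda >= 0 when calling
#'   the numeric form.
#' @param theta model angle in radians (numeric form only).
#' @param ... unused.
#' @return Named numeric(2): `lambda1`, `lambda2`.
#' @examples
#' relativeRisks(1, pi / 2)   # recessive: (1, 2)
#' @export
setMethod("relativeRisks", "GeneticModel", function(x, ...) {
  relativeRisks(x@lambda, x@theta)
})

#' @rdname relativeRisks
#' @export
setMethod("relativeRisks", "numeric", function(x, theta, ...) {
  if (length(x) != 1L || !is.finite(x) || x < 0)
    stop("lambda must be a single number >= 0")
  if (length(theta) != 1L || theta < pi / 4 - 1e-12 || theta > pi / 2 + 1e-12)
    stop("theta must lie in [pi/4, pi/2]")
  c(lambda1 = 1 + x * cos(theta), lambda2 = 1 + x * sin(theta))
})

#' Penetrances and genotype cell probabilities of a model
#'
#' Population genotype frequencies are Hardy-Weinberg:
#' `P(G) = ((1-q)^2, 2q(1-q), q^2)`. The baseline penetrance is fixed by
#' the prevalence,
#' \deqn{f_0 = K / [(1-q)^2 + 2\lambda_1 q(1-q) + \lambda_2 q^2],}
#' with `f_i = lambda_i * f0`, which enforces `sum P(G_i) f_i = K`. The
#' genotype distributions within cases and controls follow by Bayes'
#' rule: `tau_i = P(G_i) f_i / K` and `upsilon_i = P(G_i)(1 - f_i)/(1 - K)`;
#' both triples sum to 1 analytically. A parameter combination that would
#' push any penetrance to 1 or beyond is rejected as infeasible.
#'
#' @param x a [GeneticModel-class].
#' @param ... unused.
#' @return A list with `tau` (case genotype probabilities), `upsilon`
#'   (control genotype probabilities), `f` (penetrances f0, f1, f2),
#'   `lambdas` (lambda1, lambda2) and `pG` (population genotype
#'   frequencies).
#' @examples
#' m <- geneticModel(0.1, 0.2, lambda = 1, model = "recessive")
#' cellProbabilities(m)
#' @export
setMethod("cellProbabilities", "GeneticModel", function(x, ...) {
  K <- x@prevalence; q <- x@maf
  lam <- relativeRisks(x)
  pG <- c(aa = (1 - q)^2, Aa = 2 * q * (1 - q), AA = q^2)
  f0 <- K / ((1 - q)^2 + 2 * lam[["lambda1"]] * q * (1 - q) +
               lam[["lambda2"]] * q^2)
  f <- f0 * c(1, lam[["lambda1"]], lam[["lambda2"]])
  names(f) <- c("f0", "f1", "f2")
  if (any(f >= 1))
    stop(sprintf(paste0("infeasible model: penetrance reaches %g >= 1 at ",
                        "(K = %g, q = %g, lambda = %g, theta = %g)"),
                 max(f), K, q, x@lambda, x@theta))
  tau <- unname(pG) * f / K
  upsilon <- unname(pG) * (1 - f) / (1 - K)
  list(tau = stats::setNames(unname(tau), names(pG)),
       upsilon = stats::setNames(unname(upsilon), names(pG)),
       f = f, lambdas = lam, pG = pG)
})

setMethod("show", "GeneticModel", function(object) {
  lam <- relativeRisks(object)
  cat("GeneticModel\n")
  cat(sprintf("  prevalence K = %g, MAF q = %g\n",
              object@prevalence, object@maf))
  cat(sprintf("  lambda = %g, theta = %.4f rad (theta' = %.4f)\n",
              object@lambda, object@theta, object@theta / pi))
  cat(sprintf("  relative risks: lambda1 = %.4f, lambda2 = %.4f\n",
              lam[["lambda1"]], lam[["lambda2"]]))
  invisible(NULL)
})
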