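#' @rdname genotypeTable-accessors
#' @export
setGeneric("caseCounts", function(x) standardGeneric("caseCounts"))

#' @rdname genotypeTable-accessors
#' @export
setGeneric("controlCounts", function(x) standardGeneric("controlCounts"))

#' @rdname genotypeTable-accessors
#' @export
setGeneric("genotypeTotals", function(x) standardGeneric("genotypeTotals"))

#' @rdname genotypeTable-accessors
#' @export
setGeneric("nCases", function(x) standardGeneric("nCases"))

#' @rdname genotypeTable-accessors
#' @export
setGeneric("nControls", function(x) standardGeneric("nControls"))

#' @rdname genotypeTable-accessors
#' @export
setGeneric("nTotal", function(x) standardGeneric("nTotal"))

#' @rdname genotypeTable-accessors
#' @export
setGeneric("tableLabel", function(x) standardGeneric("tableLabel"))

#' @rdname genotypeTable-accessors
#' @export
setGeneric("isFractional", function(x) standardGeneric("isFractional"))

#' @rdname minorAlleleFrequency
#' @export
setGeneric("minorAlleleFrequency",
           function(x, ...) standardGeneric("minorAlleleFrequency"))

#' @rdname geneticModel-accessors
#' @export
setGeneric("prevalence", function(x) standardGeneric("prevalence"))

#' @rdname geneticModel-accessors
#' @export
setGeneric("modelTheta", function(x) standardGeneric("modelTheta"))

#' @rdname geneticModel-accessors
#' @export
setGeneric("effectDistance", function(x) standardGeneric("effectDistance"))

#' @rdname relativeRisks
#' @export
setGeneric("relativeRisks", function(x, ...) standardGeneric("relativeRisks"))

#' @rdname cellProbabilities
#' @export
setGeneric("cellProbabilities",
           function(x, ...) standardGeneric("cellProbabilities"))

#' @rdname assocTestResult-accessors
#' @export
setGeneric("statistic", function(x) standardGeneric("statistic"))

#' @rdname assocTestResult-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname assocTestResult-accessors
#' @export
setGeneric("testName", function(x) standardGeneric("testName"))
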