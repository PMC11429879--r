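#' @rdname ClockCohort
#' @param x a `ClockCohort`.
#' @export
setGeneric("ages", function(x) standardGeneric("ages"))

#' @rdname ClockReference-class
#' @param x a `ClockReference` or `AgeLikelihood`.
#' @export
setGeneric("ageGrid", function(x) standardGeneric("ageGrid"))

#' @rdname ClockReference-class
#' @export
setGeneric("referenceGenes", function(x) standardGeneric("referenceGenes"))

#' @rdname ClockReference-class
#' @export
setGeneric("expectedFreq", function(x) standardGeneric("expectedFreq"))

#' @rdname ClockReference-class
#' @export
setGeneric("geneCorrelations", function(x) standardGeneric("geneCorrelations"))

#' @rdname ClockReference-class
#' @export
setGeneric("smoothingTau", function(x) standardGeneric("smoothingTau"))

#' @rdname ClockReference-class
#' @export
setGeneric("frequencyFloor", function(x) standardGeneric("frequencyFloor"))

#' Predict transcriptomic age
#'
#' Computes the Poisson log-likelihood of observed raw counts at every age of
#' the reference grid and reports the maximum-likelihood age. See
#' the method descriptions for the single-sample (named numeric vector) and
#' cohort (`ClockCohort`) forms.
#'
#' @param x observed raw counts: a named numeric vector for one sample, or a
#'   [ClockCohort-class] for many.
#' @param reference a [ClockReference-class].
#' @param ... passed to methods.
#' @return An [AgeLikelihood-class] for a single sample; a `data.frame`
#'   (columns `sample`, `predicted_age_months`, `genes_used`, `max_loglik`)
#'   for a cohort.
#' @export
setGeneric("predictAge", function(x, reference, ...)
    standardGeneric("predictAge"))

#' @rdname AgeLikelihood-class
#' @param x an `AgeLikelihood`.
#' @export
setGeneric("predictedAge", function(x) standardGeneric("predictedAge"))

#' @rdname AgeLikelihood-class
#' @export
setGeneric("gridLogLik", function(x) standardGeneric("gridLogLik"))

#' @rdname AgeLikelihood-class
#' @export
setGeneric("genesUsed", function(x) standardGeneric("genesUsed"))

#' @rdname ValidationReport-class
#' @param x a `ValidationReport`.
#' @export
setGeneric("predictionTable", function(x) standardGeneric("predictionTable"))

#' @rdname ValidationReport-class
#' @export
setGeneric("validationMetrics", function(x)
    standardGeneric("validationMetrics"))

#' @rdname ValidationReport-class
#' @export
setGeneric("foldLog", function(x) standardGeneric("foldLog"))

#' @rdname ValidationReport-class
#' @export
setGeneric("failedFolds", function(x) standardGeneric("failedFolds"))

#' @rdname ValidationReport-class
#' @export
setGeneric("modelLabel", function(x) standardGeneric("modelLabel"))

#' @rdname ValidationReport-class
#' @export
setGeneric("reportDetails", function(x) standardGeneric("reportDetails"))
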