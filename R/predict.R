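#' Poisson log probability mass
#'
#' Log of the Poisson pmf `exp(-lambda) * lambda^k / k!`, evaluated in a
#' log-gamma-stable form so counts up to at least 1e7 neither overflow nor
#' lose precision. Vectorized over `k` and `lambda` (recycled).
#'
#' @param k non-negative integer count(s).
#' @param lambda positive rate(s).
#' @return log-probability, same length as the longer argument.
#' @examples
#' poissonLogPmf(0, 1)        # -1
#' poissonLogPmf(1e6, 1e6)    # finite, ~ -0.5*log(2*pi*1e6)
#' @export
poissonLogPmf <- function(k, lambda) {
    if (any(!is.finite(k)) || any(k < 0) || any(k != round(k)))
        stop("k must be non-negative integer(s)")
    if (any(!is.finite(lambda)) || any(lambda <= 0))
        stop("lambda must be positive")
    dpois(k, lambda, log = TRUE)
}

#' Expected count of a gene at a candidate age
#'
#' The Poisson rate for a gene at a candidate age: the reference expected
#' frequency at that age scaled by the test sample's total library size,
#' making the rate commensurable with the observed raw count.
#'
#' @param refFreq expected frequency (>= the reference floor).
#' @param sampleTotal positive total count of the test sample (all genes).
#' @return `refFreq * sampleTotal`.
#' @examples
#' expectedCount(0.001, 1e6)  # 1000
#' @export
expectedCount <- function(refFreq, sampleTotal) {
    if (any(sampleTotal <= 0)) stop("sampleTotal must be positive")
    if (any(refFreq <= 0)) stop("refFreq must be positive")
    refFreq * sampleTotal
}

#' Summed Poisson log-likelihood of a sample at one grid age
#'
#' Sum over the intersected genes of the Poisson log-pmf of the observed
#' count, at the rate implied by the reference frequency at the requested
#' grid age and the sample's total count. The log-domain sum replaces the
#' product of per-gene probabilities to avoid underflow.
#'
#' @param sampleCounts named numeric vector of observed raw counts for
#'   (at least) the reference genes present in the sample.
#' @param sampleTotal positive total count of the sample over all genes.
#' @param reference a [ClockReference-class].
#' @param ageIndex index into `ageGrid(reference)`.
#' @return scalar log-likelihood.
#' @export
ageLogLikelihood <- function(sampleCounts, sampleTotal, reference, ageIndex) {
    stopifnot(is(reference, "ClockReference"))
    genes <- intersect(referenceGenes(reference), names(sampleCounts))
    if (!length(genes)) stop("no reference genes present in the sample")
    if (length(ageIndex) != 1L || ageIndex < 1L ||
        ageIndex > length(ageGrid(reference)))
        stop("ageIndex out of range")
    lam <- expectedCount(reference@freq[genes, ageIndex], sampleTotal)
    sum(poissonLogPmf(sampleCounts[genes], lam))
}

.predictOne <- function(k, total, reference, sampleId) {
    genes <- intersect(referenceGenes(reference), names(k))
    if (!length(genes))
        stop("sample '", sampleId,
             "' shares no genes with the reference")
    lam <- reference@freq[genes, , drop = FALSE] * total
    ll <- colSums(dpois(k[genes], lam, log = TRUE))
    grid <- ageGrid(reference)
    new("AgeLikelihood", sampleId = sampleId, grid = grid,
        logLik = unname(ll), predictedAge = grid[which.max(ll)],
        genesUsed = length(genes))
}

#' @describeIn predictAge one sample: a named vector of raw counts over the
#'   sample's full gene list. Reference genes absent from the vector's names
#'   are silently dropped (missing-feature tolerance); genes present with
#'   count 0 are used, since a zero is an observation. `total` defaults to
#'   the sum over all genes in the vector. Ties in the likelihood are broken
#'   toward the youngest age.
#' @param total positive total count of the sample over all its genes;
#'   defaults to `sum(x)`.
#' @param sampleId label for the returned object.
#' @export
setMethod("predictAge", signature(x = "numeric", reference = "ClockReference"),
    function(x, reference, total = sum(x), sampleId = "sample") {
        if (is.null(names(x))) stop("counts must be named by gene id")
        if (any(x < 0) || any(x != round(x)))
            stop("counts must be non-negative integers")
        if (total <= 0) stop("sample total must be positive")
        .predictOne(x, total, reference, sampleId)
    })

#' @describeIn predictAge a cohort: one prediction per sample, returned as a
#'   data.frame with columns `sample`, `predicted_age_months`, `genes_used`
#'   and `max_loglik`.
#' @export
setMethod("predictAge",
    signature(x = "ClockCohort", reference = "ClockReference"),
    function(x, reference) {
        m <- counts(x)
        tot <- colSums(m)
        rows <- lapply(colnames(m), function(s) {
            al <- .predictOne(m[, s], tot[s], reference, s)
            data.frame(sample = s, predicted_age_months = predictedAge(al),
                       genes_used = genesUsed(al),
                       max_loglik = max(gridLogLik(al)))
        })
        out <- do.call(rbind, rows)
        rownames(out) <- NULL
        out
    })

#' @describeIn AgeLikelihood the maximum-likelihood (predicted) age, months.
#' @export
setMethod("predictedAge", "AgeLikelihood", function(x) x@predictedAge)

#' @describeIn AgeLikelihood log-likelihood at each grid age.
#' @export
setMethod("gridLogLik", "AgeLikelihood", function(x) {
    ll <- x@logLik
    names(ll) <- format(x@grid, trim = TRUE)
    ll
})

#' @describeIn AgeLikelihood the candidate-age grid (months).
#' @export
setMethod("ageGrid", "AgeLikelihood", function(x) x@grid)

#' @describeIn AgeLikelihood number of reference genes found in the sample.
#' @export
setMethod("genesUsed", "AgeLikelihood", function(x) x@genesUsed)

setMethod("show", "AgeLikelihood", function(object) {
    cat("AgeLikelihood for sample '", object@sampleId, "'\n", sep = "")
    cat("  predicted age:", object@predictedAge, "months;",
        object@genesUsed, "genes used\n")
    cat("  max log-likelihood:",
        sprintf("%.3f", max(object@logLik)), "\n")
    invisible(NULL)
})
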