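#' @import methods
#' @importFrom stats cor dpois approx lowess sd rpois rlnorm runif predict
#' @importFrom utils read.delim write.table
#' @importFrom BiocGenerics counts
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
NULL

#' ClockCohort: a bulk RNA-seq cohort with per-sample ages
#'
#' A `ClockCohort` is a [SummarizedExperiment::SummarizedExperiment] holding a
#' raw integer count matrix (genes in rows, samples in columns) in the
#' `"counts"` assay, with a mandatory numeric `age` column (months) in
#' `colData`. Validity enforces the assumptions the clock relies on:
#' non-negative integral counts, unique gene and sample identifiers, strictly
#' positive library sizes, and strictly positive ages.
#'
#' @slot .Data inherited SummarizedExperiment representation.
#' @seealso [ClockCohort()] for construction from a matrix and metadata,
#'   [readCounts()] and [readSampleMetadata()] for file ingestion.
#' @export
setClass("ClockCohort", contains = "SummarizedExperiment")

.validClockCohort <- function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is missing")
    m <- SummarizedExperiment::assay(object, "counts")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        msg <- c(msg, "counts must carry gene rownames and sample colnames")
    if (anyDuplicated(rownames(m)))
        msg <- c(msg, paste0("duplicate gene ids: ",
                             paste(unique(rownames(m)[duplicated(rownames(m))]),
                                   collapse = ", ")))
    if (anyDuplicated(colnames(m)))
        msg <- c(msg, paste0("duplicate sample ids: ",
                             paste(unique(colnames(m)[duplicated(colnames(m))]),
                                   collapse = ", ")))
    if (!all(is.finite(m)) || any(m < 0) || any(m != round(m)))
        msg <- c(msg, "counts must be finite, non-negative and integral")
    tot <- colSums(m)
    if (any(tot <= 0))
        msg <- c(msg, paste0("zero-depth sample(s): ",
                             paste(colnames(m)[tot <= 0], collapse = ", ")))
    cd <- SummarizedExperiment::colData(object)
    if (!"age" %in% colnames(cd)) {
        msg <- c(msg, "colData must contain an 'age' column (months)")
    } else {
        age <- cd$age
        if (!is.numeric(age) || anyNA(age) || any(age <= 0))
            msg <- c(msg, "ages must be positive numbers (months)")
    }
    if (length(msg)) msg else TRUE
}
setValidity("ClockCohort", .validClockCohort)

#' ClockReference: a trained transcriptomic clock
#'
#' The trained model: for each selected gene, the LOWESS-smoothed expected
#' expression frequency at every age of a discrete grid, together with the
#' gene's Spearman correlation of frequency with age, the smoothing fraction
#' `tau`, and the frequency floor applied after interpolation. Genes are
#' ordered by descending `|rho|` (ties broken by gene id).
#'
#' @slot freq numeric matrix, selected genes x grid ages; values in
#'   `[freqFloor, 1]`.
#' @slot rho named numeric vector of per-gene Spearman correlations.
#' @slot grid strictly increasing numeric vector of ages (months).
#' @slot tau LOWESS neighborhood fraction in (0, 1].
#' @slot freqFloor positive lower bound applied to fitted frequencies.
#' @seealso [buildReference()], [writeClockReference()], [predictAge()].
#' @export
setClass("ClockReference",
    representation(freq = "matrix", rho = "numeric", grid = "numeric",
                   tau = "numeric", freqFloor = "numeric"))

.validClockReference <- function(object) {
    msg <- character()
    g <- object@grid
    if (length(g) < 1L || anyNA(g) || any(diff(g) <= 0))
        msg <- c(msg, "age grid must be non-empty and strictly increasing")
    f <- object@freq
    if (nrow(f) < 1L)
        msg <- c(msg, "reference must contain at least one gene")
    if (ncol(f) != length(g))
        msg <- c(msg, "frequency matrix must have one column per grid age")
    if (is.null(rownames(f)) || anyDuplicated(rownames(f)))
        msg <- c(msg, "gene ids must be present and unique")
    ef <- object@freqFloor
    if (length(ef) != 1L || !is.finite(ef) || ef <= 0)
        msg <- c(msg, "freqFloor must be a single positive number")
    else if (any(!is.finite(f)) || any(f < ef) || any(f > 1))
        msg <- c(msg, "expected frequencies must lie in [freqFloor, 1]")
    if (length(object@tau) != 1L || object@tau <= 0 || object@tau > 1)
        msg <- c(msg, "tau must lie in (0, 1]")
    r <- object@rho
    if (length(r) != nrow(f) || !identical(names(r), rownames(f)))
        msg <- c(msg, "rho must be named identically to the frequency rows")
    else if (anyNA(r) || any(abs(r) > 1))
        msg <- c(msg, "rho values must be defined and lie in [-1, 1]")
    else {
        ord <- order(-abs(r), names(r), method = "radix")
        if (!identical(ord, seq_along(r)))
            msg <- c(msg, "genes must be sorted by descending |rho| (ties by gene id)")
    }
    if (length(msg)) msg else TRUE
}
setValidity("ClockReference", .validClockReference)

#' AgeLikelihood: the per-sample age-likelihood distribution
#'
#' The Poisson log-likelihood of one sample's observed counts at every grid
#' age, together with the maximum-likelihood (predicted) age and the number
#' of reference genes actually present in the sample.
#'
#' @slot sampleId character scalar.
#' @slot grid numeric vector of candidate ages (months).
#' @slot logLik numeric vector of log-likelihoods, one per grid age.
#' @slot predictedAge grid age attaining the maximum log-likelihood
#'   (youngest age on ties).
#' @slot genesUsed integer count of reference genes found in the sample.
#' @seealso [predictAge()].
#' @export
setClass("AgeLikelihood",
    representation(sampleId = "character", grid = "numeric",
                   logLik = "numeric", predictedAge = "numeric",
                   genesUsed = "integer"))

.validAgeLikelihood <- function(object) {
    msg <- character()
    if (length(object@logLik) != length(object@grid))
        msg <- c(msg, "one log-likelihood per grid age required")
    if (any(!is.finite(object@logLik)))
        msg <- c(msg, "log-likelihoods must be finite")
    if (length(object@predictedAge) != 1L ||
        !object@predictedAge %in% object@grid)
        msg <- c(msg, "predicted age must be a grid age")
    else if (abs(object@logLik[match(object@predictedAge, object@grid)] -
                 max(object@logLik)) > 0)
        msg <- c(msg, "predicted age must attain the maximum log-likelihood")
    if (object@genesUsed < 1L)
        msg <- c(msg, "at least one gene must have been used")
    if (length(msg)) msg else TRUE
}
setValidity("AgeLikelihood", .validAgeLikelihood)

#' ValidationReport: LOOCV predictions and summary metrics for one model
#'
#' Holds per-sample leave-one-out predictions (true age, predicted age,
#' residual = predicted - true), summary metrics (MAE in months, Pearson r,
#' R-squared both as squared Pearson and as coefficient of determination),
#' a fold log proving each sample was excluded from its own training set,
#' and any failed folds (excluded from metrics).
#'
#' @slot model character label, e.g. `"clock"` or `"elasticnet"`.
#' @slot predictions data.frame with columns `sample`, `age`, `predicted`,
#'   `residual`.
#' @slot metrics named list: `mae`, `pearson_r`, `r2_pearson`, `r2_cod`.
#' @slot foldLog data.frame with columns `fold`, `test_sample`, `n_train`,
#'   `train_samples` (semicolon-joined ids).
#' @slot failedFolds character vector of sample ids whose fold failed.
#' @slot details list of model-specific extras (e.g. the Elastic-Net
#'   hyperparameter grid with per-pair MAE).
#' @seealso [loocvClock()], [loocvElasticNet()], [residualBias()].
#' @export
setClass("ValidationReport",
    representation(model = "character", predictions = "data.frame",
                   metrics = "list", foldLog = "data.frame",
                   failedFolds = "character", details = "list"))

.validValidationReport <- function(object) {
    msg <- character()
    p <- object@predictions
    need <- c("sample", "age", "predicted", "residual")
    if (!all(need %in% colnames(p)))
        msg <- c(msg, paste0("predictions must have columns: ",
                             paste(need, collapse = ", ")))
    else if (nrow(p) > 0 &&
             max(abs(p$residual - (p$predicted - p$age))) > 1e-12)
        msg <- c(msg, "residual must equal predicted - age")
    if (!all(c("mae", "pearson_r", "r2_pearson", "r2_cod") %in%
             names(object@metrics)))
        msg <- c(msg, "metrics must contain mae, pearson_r, r2_pearson, r2_cod")
    if (length(msg)) msg else TRUE
}
setValidity("ValidationReport", .validValidationReport)
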