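#' Construct a ClockCohort from counts and sample metadata
#'
#' Joins a raw count matrix (genes x samples) with per-sample metadata into a
#' validated [ClockCohort-class]. Every sample column of `counts` must appear
#' exactly once in `metadata`; metadata rows are reordered to the column
#' order of `counts`. Extra metadata columns (tissue, sex, ...) are kept as
#' opaque covariates in `colData`.
#'
#' @param counts numeric matrix of non-negative integral counts with gene
#'   rownames and sample colnames. Genes with all-zero counts are retained;
#'   they simply have an undefined Spearman correlation downstream.
#' @param metadata data.frame with a `sample` column (or sample rownames) and
#'   a positive numeric `age` column in months.
#' @return A [ClockCohort-class].
#' @examples
#' m <- matrix(c(2L, 3L, 5L, 0L, 1L, 9L), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' meta <- data.frame(sample = c("s1", "s2"), age = c(3, 24))
#' cohort <- ClockCohort(m, meta)
#' ages(cohort)
#' @export
ClockCohort <- function(counts, metadata) {
    if (!is.matrix(counts) || !is.numeric(counts))
        stop("'counts' must be a numeric matrix")
    if (!is.data.frame(metadata))
        stop("'metadata' must be a data.frame")
    ids <- if ("sample" %in% colnames(metadata)) as.character(metadata$sample)
           else rownames(metadata)
    if (is.null(ids))
        stop("'metadata' needs a 'sample' column or sample rownames")
    if (anyDuplicated(ids))
        stop("duplicate sample ids in metadata: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    if (!"age" %in% colnames(metadata))
        stop("'metadata' needs an 'age' column (months)")
    missing <- setdiff(colnames(counts), ids)
    if (length(missing))
        stop("sample(s) in counts but absent from metadata: ",
             paste(missing, collapse = ", "))
    metadata <- metadata[match(colnames(counts), ids), , drop = FALSE]
    cd <- S4Vectors::DataFrame(metadata, row.names = colnames(counts))
    cd$sample <- NULL
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    new("ClockCohort", se)
}

#' @describeIn ClockCohort sample ages in months.
#' @export
setMethod("ages", "ClockCohort", function(x)
    SummarizedExperiment::colData(x)$age)

#' @describeIn ClockCohort the raw count matrix (genes x samples).
#' @param object a `ClockCohort`.
#' @export
setMethod("counts", "ClockCohort", function(object)
    SummarizedExperiment::assay(object, "counts"))

setMethod("show", "ClockCohort", function(object) {
    a <- ages(object)
    cat("ClockCohort:", nrow(object), "genes x", ncol(object), "samples\n")
    cat("  ages (months): ", paste(range(a), collapse = "-"),
        " (", length(unique(a)), " distinct)\n", sep = "")
    cat("  library sizes: ",
        paste(format(range(colSums(counts(object))), big.mark = ","),
              collapse = " - "), "\n", sep = "")
    invisible(NULL)
})
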