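## Delimited-text ingestion and the on-disk reference format.
## Counts/metadata follow the GEO supplementary-matrix convention: TSV
## (comma auto-detected), first column = ids, header row = the other axis.
## Lines starting with '#' are treated as comments in all three formats.

.detectSep <- function(path) {
    first <- readLines(path, n = 50L)
    first <- first[!startsWith(first, "#")]
    if (!length(first)) stop("no data lines in ", path)
    if (lengths(regmatches(first[1], gregexpr("\t", first[1]))) > 0) "\t"
    else ","
}

.numericCells <- function(df, path) {
    ## df: character data.frame of the value block (ids already stripped)
    out <- matrix(NA_real_, nrow(df), ncol(df))
    for (j in seq_len(ncol(df))) {
        v <- suppressWarnings(as.numeric(df[[j]]))
        bad <- which(is.na(v) & !is.na(df[[j]]))
        if (length(bad))
            stop("non-numeric value '", df[[j]][bad[1]], "' at row ", bad[1],
                 ", column '", colnames(df)[j], "' of ", path)
        out[, j] <- v
    }
    colnames(out) <- colnames(df)
    out
}

#' Read a raw count matrix from delimited text
#'
#' Reads a TSV (comma auto-detected) count table with a header row. With the
#' default orientation the first column holds gene ids and the remaining
#' columns are samples; with `orientation = "samples"` the file is the
#' transpose (first column sample ids, header gene ids) and is transposed
#' back on read, so both orientations of the same data yield identical
#' matrices. Entries must be non-negative integers; duplicate ids,
#' non-numeric cells and zero-total samples are rejected with the offending
#' name in the message.
#'
#' @param path file path.
#' @param orientation `"genes"` (rows are genes, default) or `"samples"`.
#' @return numeric matrix, genes x samples.
#' @seealso [ClockCohort()] to join with metadata, [writeCounts()].
#' @export
readCounts <- function(path, orientation = c("genes", "samples")) {
    orientation <- match.arg(orientation)
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- .detectSep(path)
    df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                     colClasses = "character", comment.char = "#")
    if (ncol(df) < 2L) stop("count table needs an id column plus data: ", path)
    ids <- df[[1]]
    m <- .numericCells(df[-1], path)
    rownames(m) <- ids
    if (orientation == "samples") m <- t(m)
    if (anyDuplicated(rownames(m)))
        stop("duplicate gene ids: ",
             paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
    if (anyDuplicated(colnames(m)))
        stop("duplicate sample ids: ",
             paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
    if (any(m < 0) || any(m != round(m)))
        stop("counts must be non-negative integers in ", path)
    tot <- colSums(m)
    if (any(tot <= 0))
        stop("zero-total sample(s): ",
             paste(colnames(m)[tot <= 0], collapse = ", "))
    m
}

#' Read per-sample metadata
#'
#' Reads a delimited table with a `sample` id column (or the first column if
#' none is named `sample`) and an `age` column in months. Additional columns
#' are preserved untouched as covariates.
#'
#' @param path file path.
#' @return data.frame with at least columns `sample` (character) and `age`
#'   (positive numeric, months).
#' @export
readSampleMetadata <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- .detectSep(path)
    df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                     comment.char = "#")
    if (!"sample" %in% colnames(df)) colnames(df)[1] <- "sample"
    if (!"age" %in% colnames(df))
        stop("metadata needs an 'age' column (months): ", path)
    df$sample <- as.character(df$sample)
    df$age <- suppressWarnings(as.numeric(df$age))
    if (anyNA(df$age)) stop("missing or non-numeric age in ", path)
    if (any(df$age <= 0))
        stop("non-positive age for sample(s): ",
             paste(df$sample[df$age <= 0], collapse = ", "))
    df
}

#' Write cohort counts / metadata back to TSV
#'
#' Inverse of [readCounts()] / [readSampleMetadata()]: round-trips to
#' identical objects. Optional `header` lines are written as `#`-prefixed
#' comments before the table.
#'
#' @param x a [ClockCohort-class].
#' @param path output file.
#' @param header optional character vector of comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
writeCounts <- function(x, path, header = character()) {
    m <- counts(x)
    con <- file(path, "w")
    on.exit(close(con))
    if (length(header)) writeLines(paste0("# ", header), con)
    writeLines(paste(c("gene", colnames(m)), collapse = "\t"), con)
    body <- apply(format(m, scientific = FALSE, trim = TRUE), 1L,
                  paste, collapse = "\t")
    writeLines(paste(rownames(m), body, sep = "\t"), con)
    invisible(path)
}

#' @rdname writeCounts
#' @export
writeSampleMetadata <- function(x, path, header = character()) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    df <- data.frame(sample = colnames(x), cd, check.names = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    if (length(header)) writeLines(paste0("# ", header), con)
    writeLines(paste(colnames(df), collapse = "\t"), con)
    writeLines(do.call(paste, c(lapply(df, function(v)
        if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)),
        sep = "\t")), con)
    invisible(path)
}

.fmt <- function(x) sprintf("%.17g", x)

#' Serialize / deserialize a trained ClockReference
#'
#' The reference is stored as a TSV with one row per selected gene: columns
#' `gene`, `rho`, `rank`, then one frequency column per grid age. A
#' `#`-prefixed header block records the smoothing fraction (`#tau=`), the
#' frequency floor (`#freq_floor=`) and the grid (`#grid=` comma-separated
#' months). Numbers are written with 17 significant digits so the
#' write-read round trip is exact.
#'
#' @param reference a [ClockReference-class].
#' @param path file path.
#' @return `writeClockReference` returns `path` invisibly;
#'   `readClockReference` returns a [ClockReference-class].
#' @export
writeClockReference <- function(reference, path) {
    stopifnot(is(reference, "ClockReference"))
    validObject(reference)
    f <- expectedFreq(reference)
    g <- ageGrid(reference)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("#tau=", .fmt(smoothingTau(reference))),
                 paste0("#freq_floor=", .fmt(frequencyFloor(reference))),
                 paste0("#grid=", paste(.fmt(g), collapse = ","))), con)
    writeLines(paste(c("gene", "rho", "rank",
                       paste0("age_", format(g, trim = TRUE))),
                     collapse = "\t"), con)
    rho <- geneCorrelations(reference)
    for (i in seq_len(nrow(f)))
        writeLines(paste(c(rownames(f)[i], .fmt(rho[i]), i, .fmt(f[i, ])),
                         collapse = "\t"), con)
    invisible(path)
}

#' @rdname writeClockReference
#' @export
readClockReference <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "#")]
    getv <- function(key) {
        hit <- hdr[startsWith(hdr, paste0("#", key, "="))]
        if (length(hit) != 1L)
            stop("malformed reference header: expected one '#", key,
                 "=' line in ", path)
        sub(paste0("^#", key, "="), "", hit)
    }
    tau <- as.numeric(getv("tau"))
    floorv <- as.numeric(getv("freq_floor"))
    grid <- as.numeric(strsplit(getv("grid"), ",")[[1]])
    if (anyNA(c(tau, floorv, grid)))
        stop("malformed reference header: non-numeric tau/floor/grid in ", path)
    df <- read.delim(text = lines[!startsWith(lines, "#")], sep = "\t",
                     header = TRUE, check.names = FALSE)
    if (ncol(df) != 3L + length(grid))
        stop("reference body has ", ncol(df) - 3L,
             " frequency columns but the grid has ", length(grid), " ages")
    f <- as.matrix(df[, -(1:3), drop = FALSE])
    rownames(f) <- df$gene
    colnames(f) <- NULL
    if (any(!is.finite(f)) || any(f <= 0) || any(f > 1))
        stop("reference frequencies must lie in (0, 1]: ", path)
    rho <- df$rho
    names(rho) <- df$gene
    new("ClockReference", freq = f, rho = rho, grid = grid, tau = tau,
        freqFloor = floorv)
}

#' @describeIn ClockReference selected gene ids, ranked by descending
#'   absolute Spearman correlation.
#' @export
setMethod("referenceGenes", "ClockReference", function(x) rownames(x@freq))

#' @describeIn ClockReference the age grid (months).
#' @export
setMethod("ageGrid", "ClockReference", function(x) x@grid)

#' @describeIn ClockReference expected-frequency matrix (genes x grid ages).
#' @export
setMethod("expectedFreq", "ClockReference", function(x) {
    f <- x@freq
    colnames(f) <- format(x@grid, trim = TRUE)
    f
})

#' @describeIn ClockReference per-gene Spearman rho (signed).
#' @export
setMethod("geneCorrelations", "ClockReference", function(x) x@rho)

#' @describeIn ClockReference LOWESS neighborhood fraction tau.
#' @export
setMethod("smoothingTau", "ClockReference", function(x) x@tau)

#' @describeIn ClockReference frequency floor applied to fitted values.
#' @export
setMethod("frequencyFloor", "ClockReference", function(x) x@freqFloor)

setMethod("show", "ClockReference", function(object) {
    cat("ClockReference:", nrow(object@freq), "genes,",
        length(object@grid), "grid ages (",
        paste(range(object@grid), collapse = "-"), "months )\n")
    cat("  tau =", object@tau, "; frequency floor =", object@freqFloor, "\n")
    r <- object@rho
    cat("  |rho| range: ", sprintf("%.3f", min(abs(r))), " - ",
        sprintf("%.3f", max(abs(r))), "\n", sep = "")
    cat("  top genes:", paste(utils::head(names(r), 5), collapse = ", "),
        if (length(r) > 5) "...", "\n")
    invisible(NULL)
})
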