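#' Default candidate-age grid
#'
#' The sampled ages of the mouse cohort the clock was designed around:
#' 1, 3, 6, 9, 12, 15, 18, 21, 24 and 27 months. Likelihoods are evaluated
#' at each of these ages and the prediction is the grid argmax.
#'
#' @return numeric vector of 10 ages (months).
#' @export
defaultAgeGrid <- function() c(1, 3, 6, 9, 12, 15, 18, 21, 24, 27)

#' Normalize raw counts to compositional frequencies
#'
#' Frequency-count normalization: each count is divided by the total count
#' of its sample, so each sample's frequencies sum to 1 and are comparable
#' across sequencing depths.
#'
#' @param x a [ClockCohort-class] or a numeric count matrix (genes x
#'   samples) with positive column totals.
#' @return numeric matrix of the same shape; every column sums to 1.
#' @examples
#' normalizeFrequencies(matrix(c(2, 3, 5), 3, 1,
#'                             dimnames = list(paste0("g", 1:3), "s1")))
#' @export
normalizeFrequencies <- function(x) {
    m <- if (is(x, "ClockCohort")) counts(x) else x
    if (!is.matrix(m) || !is.numeric(m))
        stop("'x' must be a ClockCohort or a numeric matrix")
    tot <- colSums(m)
    if (any(tot <= 0))
        stop("zero-total sample(s): ",
             paste(colnames(m)[tot <= 0], collapse = ", "))
    sweep(m, 2L, tot, "/")
}

#' Spearman rank correlation with an explicit undefined state
#'
#' Pearson correlation of average-ranked values (ties get average ranks).
#' When either vector is constant the correlation is not defined; this is
#' reported as `NA` rather than an error, so constant genes can simply be
#' excluded from ranking.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return a single number in `[-1, 1]`, or `NA` when undefined.
#' @export
spearmanRho <- function(x, y) {
    if (length(x) != length(y))
        stop("'x' and 'y' must have equal length")
    if (length(x) < 3L) stop("need at least 3 observations")
    if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
    suppressWarnings(cor(x, y, method = "spearman"))
}

## all-genes Spearman against age in one call; NA for constant genes
.spearmanAll <- function(freq, ages) {
    r <- suppressWarnings(cor(t(freq), ages, method = "spearman"))[, 1L]
    names(r) <- rownames(freq)
    r
}

#' LOWESS trend of gene frequency versus age
#'
#' Locally weighted linear regression (tri-cube weights) of a gene's
#' frequency against age, with robustifying iterations, returning one
#' smoothed frequency per distinct observed age in ascending order.
#' Replicate samples at the same age enter as separate points. The
#' neighborhood fraction `tau` controls smoothness: small values track the
#' data closely (overfit risk), values near 1 approach a global line.
#'
#' @param freq numeric vector of per-sample frequencies for one gene.
#' @param ages numeric vector of matching sample ages (months); at least 3
#'   distinct values required.
#' @param tau neighborhood fraction in (0, 1].
#' @param iterations robustifying iterations (default 3).
#' @return named numeric vector of fitted frequencies at the distinct
#'   observed ages, ascending.
#' @examples
#' a <- rep(c(1, 9, 18, 27), each = 2)
#' fitLowessTrend(0.001 * a + rnorm(8, 0, 1e-5), a, tau = 0.7)
#' @export
fitLowessTrend <- function(freq, ages, tau, iterations = 3L) {
    if (length(freq) != length(ages))
        stop("'freq' and 'ages' must have equal length")
    if (length(tau) != 1L || !is.finite(tau) || tau <= 0 || tau > 1)
        stop("tau must lie in (0, 1]")
    ua <- sort(unique(ages))
    if (length(ua) < 3L)
        stop("need at least 3 distinct ages, got ", length(ua))
    fit <- lowess(ages, freq, f = tau, iter = iterations, delta = 0)
    out <- vapply(split(fit$y, fit$x), mean, numeric(1))
    out <- out[order(as.numeric(names(out)))]
    names(out) <- format(ua, trim = TRUE)
    out
}

#' Evaluate a fitted trend on the age grid
#'
#' Linear interpolation of the fitted frequencies between observed ages;
#' grid ages outside the observed range are clamped to the nearest endpoint
#' value. Results are floored at `freqFloor` (guarding against LOWESS
#' undershoot below zero) and capped at 1.
#'
#' @param fitted numeric vector of fitted frequencies at `fittedAges`.
#' @param fittedAges ascending numeric vector of the ages of `fitted`.
#' @param grid numeric vector of target ages (non-empty).
#' @param freqFloor positive lower bound (default `1e-9`).
#' @return numeric vector of frequencies at `grid`, in `[freqFloor, 1]`.
#' @examples
#' evaluateOnGrid(c(0.002, 0.004), c(1, 3), grid = c(0.5, 2, 3))
#' @export
evaluateOnGrid <- function(fitted, fittedAges, grid, freqFloor = 1e-9) {
    if (length(grid) < 1L) stop("grid must be non-empty")
    if (length(fitted) != length(fittedAges))
        stop("'fitted' and 'fittedAges' must have equal length")
    y <- approx(fittedAges, fitted, xout = grid, rule = 2)$y
    pmin(pmax(y, freqFloor), 1)
}

#' Train a transcriptomic clock reference
#'
#' The training step: counts are normalized to frequencies, each gene's
#' frequency-age trend is smoothed with LOWESS (fraction `tau`), genes are
#' ranked by the absolute Spearman correlation of frequency with age
#' (undefined correlations from constant genes are excluded), and the top
#' `nGenes` genes are kept. Each kept gene carries its smoothed expected
#' frequency at every grid age.
#'
#' @param cohort a [ClockCohort-class].
#' @param tau LOWESS neighborhood fraction in (0, 1] (default 0.7).
#' @param nGenes number of top-ranked genes to keep (default 12).
#' @param grid candidate ages in months (default [defaultAgeGrid()]).
#' @param freqFloor positive floor applied to grid frequencies
#'   (default `1e-9`).
#' @param iterations LOWESS robustifying iterations (default 3).
#' @return a [ClockReference-class].
#' @seealso [predictAge()], [writeClockReference()].
#' @export
buildReference <- function(cohort, tau = 0.7, nGenes = 12L,
                           grid = defaultAgeGrid(), freqFloor = 1e-9,
                           iterations = 3L) {
    stopifnot(is(cohort, "ClockCohort"))
    if (length(nGenes) != 1L || nGenes < 1L || nGenes != round(nGenes))
        stop("nGenes must be a positive integer")
    age <- ages(cohort)
    freq <- normalizeFrequencies(cohort)
    rho <- .spearmanAll(freq, age)
    rankable <- !is.na(rho)
    if (nGenes > sum(rankable))
        stop("nGenes = ", nGenes, " exceeds the ", sum(rankable),
             " genes with a defined Spearman correlation")
    rho <- rho[rankable]
    ord <- order(-abs(rho), names(rho), method = "radix")
    keep <- names(rho)[ord][seq_len(nGenes)]
    fmat <- matrix(NA_real_, nGenes, length(grid),
                   dimnames = list(keep, NULL))
    ua <- sort(unique(age))
    for (g in keep) {
        fit <- fitLowessTrend(freq[g, ], age, tau, iterations)
        fmat[g, ] <- evaluateOnGrid(fit, ua, grid, freqFloor)
    }
    new("ClockReference", freq = fmat, rho = rho[keep],
        grid = as.numeric(grid), tau = tau, freqFloor = freqFloor)
}
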