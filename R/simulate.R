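## Synthetic cohorts mimicking the design of an aging bulk RNA-seq study:
## samples at discrete ages spanning 1-27 months, library sizes of 1e5-1e7
## reads, a minority of genes with smooth monotone frequency-age
## trajectories and the rest age-independent, counts Poisson around
## frequency x depth. Signal genes are generated as mirrored up/down pairs
## of equal mass so the compositional remainder is exactly age-invariant.

#' Mean frequency trajectory of a signal gene
#'
#' Smooth monotone mean-frequency curves over the 1-27 month range, each
#' scaled so that `f(1) = baseline` and `f(27) = baseline * effect`
#' (an `effect` below 1 gives a decreasing variant). The `"logistic"`
#' family has its steepest change in the last third of the range,
#' mimicking expression changes that accelerate in old age.
#'
#' @param family `"linear"`, `"exponential"` or `"logistic"`.
#' @param baseline frequency at age 1 (in (0, 1)).
#' @param effect fold change over the age range (positive).
#' @param age age(s) in months, within `[1, 27]`.
#' @return mean frequency at `age`.
#' @examples
#' trajectoryFrequency("linear", 1e-4, 2, c(1, 14, 27))
#' @export
trajectoryFrequency <- function(family = c("linear", "exponential",
                                           "logistic"),
                                baseline, effect, age) {
    family <- match.arg(family)
    if (any(age < 1 | age > 27)) stop("age must lie within [1, 27] months")
    if (any(baseline <= 0) || any(effect <= 0))
        stop("baseline and effect must be positive")
    u <- (age - 1) / 26
    switch(family,
        linear = baseline * (1 + (effect - 1) * u),
        exponential = baseline * effect^u,
        logistic = {
            sig <- function(v) 1 / (1 + exp(-12 * (v - 0.75)))
            baseline * (1 + (effect - 1) *
                        (sig(u) - sig(0)) / (sig(1) - sig(0)))
        })
}

#' Specify a synthetic cohort
#'
#' Validated parameter bundle for [simulateCohort()]. Defaults describe the
#' headline simulation: 40 samples at ages drawn from the 10-age default
#' grid, 200 signal genes (alternating linear/logistic trajectories, 2-fold
#' effects, generated as mirrored up/down pairs), 1,800 age-independent
#' noise genes, and log-normal library sizes centred on 1e6 reads.
#'
#' @param nSamples number of samples.
#' @param ages optional fixed age vector (months); by default ages are
#'   drawn from `grid` with replacement.
#' @param nSignalGenes number of age-associated genes (pairs of mirrored
#'   up/down trajectories; an odd count leaves one unpaired).
#' @param nNoiseGenes number of age-independent genes.
#' @param families trajectory families cycled over signal pairs.
#' @param baselineRange range of baseline frequencies, sampled
#'   log-uniformly.
#' @param effect fold change over the 1-27 month range for signal genes.
#' @param depthMeanLog,depthSdLog log-normal library-size parameters.
#' @param overdispersion gamma-Poisson overdispersion (0 = pure Poisson;
#'   positive values multiply each rate by a Gamma(1/v, 1/v) draw).
#' @param grid age grid the cohort is sampled from.
#' @param seed integer seed; fully determines the simulated output.
#' @return a validated `cohortSpec` list.
#' @export
cohortSpec <- function(nSamples = 40L, ages = NULL, nSignalGenes = 200L,
                       nNoiseGenes = 1800L,
                       families = c("linear", "logistic"),
                       baselineRange = c(1e-5, 1e-4), effect = 2,
                       depthMeanLog = log(1e6), depthSdLog = 0.3,
                       overdispersion = 0, grid = defaultAgeGrid(),
                       seed = 1L) {
    spec <- list(nSamples = as.integer(nSamples), ages = ages,
                 nSignalGenes = as.integer(nSignalGenes),
                 nNoiseGenes = as.integer(nNoiseGenes), families = families,
                 baselineRange = baselineRange, effect = effect,
                 depthMeanLog = depthMeanLog, depthSdLog = depthSdLog,
                 overdispersion = overdispersion, grid = grid,
                 seed = as.integer(seed))
    if (spec$nSamples < 1L) stop("nSamples must be >= 1")
    if (!is.null(ages) && length(ages) != spec$nSamples)
        stop("'ages' must have one entry per sample")
    if (spec$nSignalGenes < 0L || spec$nNoiseGenes < 0L)
        stop("gene counts must be non-negative")
    if (spec$nSignalGenes + spec$nNoiseGenes < 1L)
        stop("need at least one gene")
    if (length(baselineRange) != 2L || any(baselineRange <= 0) ||
        diff(baselineRange) < 0)
        stop("baselineRange must be an increasing pair of positive values")
    if (effect <= 0) stop("effect must be positive")
    if (overdispersion < 0) stop("overdispersion must be >= 0")
    ## worst-case composition bound: every gene at max baseline and max fold
    bound <- (spec$nSignalGenes + spec$nNoiseGenes) * baselineRange[2] *
        max(effect, 1 / effect, 1) + baselineRange[2]
    if (bound >= 1)
        stop("frequency composition can exceed 1 (worst-case mass ",
             signif(bound, 3), "); lower baselineRange or gene counts")
    class(spec) <- "cohortSpec"
    spec
}

#' Simulate a synthetic aging cohort
#'
#' Draws sample ages and library sizes, builds per-gene mean-frequency
#' trajectories, and samples counts `count(g, s) ~ Poisson(f_g(age_s) *
#' depth_s)`. A filler `remainder` gene absorbs the frequency mass not
#' assigned to signal or noise genes so each sample's mean frequencies form
#' a valid composition; because signal genes come in mirrored up/down
#' pairs, the remainder's mean frequency is age-invariant. The seed in the
#' spec fully determines the output.
#'
#' @param spec a [cohortSpec()].
#' @return list with `cohort` (a [ClockCohort-class]), and `truth`: the
#'   signal-gene table (`gene`, `family`, `baseline`, `effect`,
#'   `direction`), the signal gene ids, and the noiseless mean-frequency
#'   matrix of the signal genes at the spec's grid ages (`gridFreq`).
#' @examples
#' sim <- simulateCohort(cohortSpec(nSamples = 8, nSignalGenes = 4,
#'                                  nNoiseGenes = 20, seed = 7))
#' sim$cohort
#' @export
simulateCohort <- function(spec) {
    stopifnot(inherits(spec, "cohortSpec"))
    set.seed(spec$seed)
    n <- spec$nSamples
    age <- if (is.null(spec$ages)) sample(spec$grid, n, replace = TRUE)
           else as.numeric(spec$ages)
    depth <- round(rlnorm(n, spec$depthMeanLog, spec$depthSdLog))
    depth[depth < 1] <- 1

    nSig <- spec$nSignalGenes
    nPairs <- nSig %/% 2L
    nUp <- nPairs + nSig %% 2L
    fam <- rep_len(spec$families, nUp)
    bl <- exp(runif(nUp, log(spec$baselineRange[1]),
                    log(spec$baselineRange[2])))
    sigGenes <- character(0)
    truth <- data.frame(gene = character(), family = character(),
                        baseline = numeric(), effect = numeric(),
                        direction = character())
    meanAt <- function(a) {       # signal-gene mean frequencies at age(s) a
        rows <- list()
        for (i in seq_len(nUp)) {
            up <- trajectoryFrequency(fam[i], bl[i], spec$effect, a)
            rows[[length(rows) + 1L]] <- up
            if (i <= nPairs)      # mirrored partner: constant pair mass
                rows[[length(rows) + 1L]] <- bl[i] * (1 + spec$effect) - up
        }
        do.call(rbind, rows)
    }
    if (nSig > 0L) {
        for (i in seq_len(nUp)) {
            id <- sprintf("sig%04d_%s_up", i, fam[i])
            sigGenes <- c(sigGenes, id)
            truth <- rbind(truth, data.frame(gene = id, family = fam[i],
                                             baseline = bl[i],
                                             effect = spec$effect,
                                             direction = "up"))
            if (i <= nPairs) {
                id2 <- sprintf("sig%04d_%s_dn", i, fam[i])
                sigGenes <- c(sigGenes, id2)
                truth <- rbind(truth,
                               data.frame(gene = id2, family = fam[i],
                                          baseline = bl[i],
                                          effect = spec$effect,
                                          direction = "down"))
            }
        }
    }
    noiseGenes <- if (spec$nNoiseGenes > 0L)
        sprintf("noise%05d", seq_len(spec$nNoiseGenes)) else character(0)
    noiseFreq <- exp(runif(spec$nNoiseGenes, log(spec$baselineRange[1]),
                           log(spec$baselineRange[2])))

    M <- matrix(0, nSig + spec$nNoiseGenes + 1L, n,
                dimnames = list(c(sigGenes, noiseGenes, "remainder"),
                                sprintf("s%03d", seq_len(n))))
    if (nSig > 0L) M[sigGenes, ] <- meanAt(age)
    if (spec$nNoiseGenes > 0L)
        M[noiseGenes, ] <- matrix(noiseFreq, spec$nNoiseGenes, n)
    rem <- 1 - colSums(M)
    if (any(rem < 0)) stop("frequency composition exceeds 1")
    M["remainder", ] <- rem

    lam <- sweep(M, 2L, depth, "*")
    if (spec$overdispersion > 0) {
        v <- spec$overdispersion
        lam <- lam * matrix(stats::rgamma(length(lam), 1 / v, 1 / v),
                            nrow(lam))
    }
    cts <- matrix(as.double(rpois(length(lam), lam)), nrow(lam),
                  dimnames = dimnames(M))
    meta <- data.frame(sample = colnames(cts), age = age)
    gridFreq <- if (nSig > 0L) {
        gf <- meanAt(spec$grid)
        dimnames(gf) <- list(sigGenes, format(spec$grid, trim = TRUE))
        gf
    } else NULL
    list(cohort = ClockCohort(cts, meta),
         truth = list(signal = truth, signalGenes = sigGenes,
                      gridFreq = gridFreq, depth = depth))
}
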