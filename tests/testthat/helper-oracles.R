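## Independent brute-force oracles and small fixture builders. The oracles
## deliberately avoid the code paths they check: average ranks and the
## Pearson formula are written out by hand, the Poisson pmf is evaluated in
## linear space, and the log-pmf oracle uses the explicit log-gamma form.

## average ranks (ties -> mean of the positions they span)
averageRanks <- function(x) {
    ord <- order(x)
    r <- numeric(length(x))
    i <- 1L
    while (i <= length(x)) {
        j <- i
        while (j < length(x) && x[ord[j + 1L]] == x[ord[i]]) j <- j + 1L
        r[ord[i:j]] <- mean(i:j)
        i <- j + 1L
    }
    r
}

## Pearson from first principles
pearsonOracle <- function(x, y) {
    n <- length(x)
    sx <- x - sum(x) / n
    sy <- y - sum(y) / n
    sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
}

spearmanOracle <- function(x, y) {
    if (min(x) == max(x) || min(y) == max(y)) return(NA_real_)
    pearsonOracle(averageRanks(x), averageRanks(y))
}

## naive Poisson pmf in linear space (small k only)
naivePoissonPmf <- function(k, lam) exp(-lam) * lam^k / factorial(k)

## explicit log-gamma form of the log-pmf
logGammaPoissonLogPmf <- function(k, lam) k * log(lam) - lam - lgamma(k + 1)

## a tiny deterministic cohort: nGenes x nSamples, ages cycled over grid
tinyCohort <- function(nGenes = 30L, nSamples = 20L, seed = 42L,
                       grid = defaultAgeGrid()) {
    set.seed(seed)
    age <- rep_len(grid, nSamples)
    m <- matrix(rpois(nGenes * nSamples, 50), nGenes, nSamples,
                dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                                sprintf("s%03d", seq_len(nSamples))))
    ClockCohort(m, data.frame(sample = colnames(m), age = age))
}

## total curvature of a fitted curve: sum of squared second differences
totalCurvature <- function(y) sum(diff(y, differences = 2L)^2)

## a fixed noisy logistic frequency trajectory over replicated grid ages
noisyLogisticFixture <- function(seed = 99L) {
    set.seed(seed)
    ages <- rep(defaultAgeGrid(), each = 4L)
    f <- trajectoryFrequency("logistic", 1e-3, 3, ages)
    list(ages = ages, freq = f * exp(rnorm(length(ages), 0, 0.15)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
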