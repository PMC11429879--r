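test_that("Poisson log-pmf matches closed forms and stays stable at 1e6", {
    expect_equal(poissonLogPmf(0, 1), -1)
    expect_equal(poissonLogPmf(2, 2), 2 * log(2) - 2 - log(2))
    ## log-gamma oracle at large counts: finite, no overflow
    v <- poissonLogPmf(1e6, 1e6)
    expect_true(is.finite(v))
    expect_equal(v, logGammaPoissonLogPmf(1e6, 1e6), tolerance = 1e-6)
    ## naive pmf cross-check for small k
    for (k in 0:20)
        expect_equal(poissonLogPmf(k, 3.7), log(naivePoissonPmf(k, 3.7)),
                     tolerance = 1e-9)
    expect_error(poissonLogPmf(2, 0), "lambda")
    expect_error(poissonLogPmf(-1, 2), "k")
    expect_error(poissonLogPmf(1.5, 2), "k")
})

test_that("expected count scales reference frequency by library size", {
    expect_equal(expectedCount(0.001, 1e6), 1000)
    expect_equal(expectedCount(1e-9, 1e6), 1e-3)
    f <- c(1e-4, 5e-3, 0.2)
    expect_equal(expectedCount(f, 2e6), 2 * expectedCount(f, 1e6))
    expect_error(expectedCount(0.1, 0), "positive")
})

mkRef <- function(freqMat, grid) {
    rho <- seq(0.99, 0.5, length.out = nrow(freqMat))
    names(rho) <- rownames(freqMat)
    f <- freqMat
    new("ClockReference", freq = f, rho = rho, grid = grid, tau = 0.7,
        freqFloor = 1e-9)
}

test_that("summed log-likelihood equals the brute-force product", {
    f <- matrix(c(1e-4, 3e-4, 2e-4, 5e-4, 8e-4, 6e-4), 3, 2,
                dimnames = list(c("gA", "gB", "gC"), NULL))
    ref <- mkRef(f, grid = c(1, 9))
    k <- c(gA = 2, gB = 0, gC = 5)
    tot <- 1e4
    for (a in 1:2) {
        ll <- ageLogLikelihood(k, tot, ref, a)
        prod <- prod(naivePoissonPmf(k, f[, a] * tot))
        expect_equal(ll, log(prod), tolerance = 1e-9)
    }
    ## single gene reduces to the pmf itself
    ref1 <- mkRef(f[1, , drop = FALSE], grid = c(1, 9))
    expect_equal(ageLogLikelihood(k["gA"], tot, ref1, 1),
                 poissonLogPmf(2, f[1, 1] * tot))
    ## permuting gene order leaves the value unchanged
    expect_equal(ageLogLikelihood(k[c(3, 1, 2)], tot, ref, 1),
                 ageLogLikelihood(k, tot, ref, 1))
    expect_error(ageLogLikelihood(c(zz = 1), tot, ref, 1), "no reference")
})

test_that("single-gene prediction lands on the age whose rate equals k", {
    ## lambda grid {1000, 3000}, observed k = 3000 -> 3 months
    f <- matrix(c(0.001, 0.003), 1, 2, dimnames = list("gA", NULL))
    ref <- mkRef(f, grid = c(1, 3))
    al <- predictAge(c(gA = 3000, other = 997000), ref)
    expect_equal(predictedAge(al), 3)
    expect_equal(genesUsed(al), 1L)

    ## randomized constructions: the grid age matching the count wins
    set.seed(31)
    for (i in 1:50) {
        grid <- sort(sample(defaultAgeGrid(), 4))
        freqs <- 1e-4 + cumsum(runif(4, 1e-4, 1.2e-3))  # well-separated rates
        target <- sample(4, 1)
        tot <- 1e6
        k <- round(freqs[target] * tot)
        ref <- mkRef(matrix(freqs, 1, dimnames = list("gA", NULL)), grid)
        al <- predictAge(c(gA = k), ref, total = tot)
        expect_equal(predictedAge(al), grid[target])
    }
})

test_that("reference genes missing from the sample are tolerated", {
    sim <- simulateCohort(cohortSpec(nSamples = 20, nSignalGenes = 20,
                                     nNoiseGenes = 50, seed = 17))
    ref <- buildReference(sim$cohort, nGenes = 12)
    k <- counts(sim$cohort)[, 1]
    tot <- sum(k)
    drop <- referenceGenes(ref)[1:5]
    al <- predictAge(k[setdiff(names(k), drop)], ref, total = tot,
                     sampleId = "s1")
    expect_equal(genesUsed(al), 7L)
    expect_true(predictedAge(al) %in% defaultAgeGrid())
    ## zero counts are observations, not missing features
    k0 <- k; k0[referenceGenes(ref)[1]] <- 0
    expect_equal(genesUsed(predictAge(k0, ref, total = tot)), 12L)
})

test_that("prediction is invariant to gene order in sample and reference", {
    sim <- simulateCohort(cohortSpec(nSamples = 12, nSignalGenes = 10,
                                     nNoiseGenes = 30, seed = 19))
    ref <- buildReference(sim$cohort, nGenes = 6)
    k <- counts(sim$cohort)[, 3]
    set.seed(1)
    al1 <- predictAge(k, ref)
    al2 <- predictAge(k[sample(names(k))], ref)
    expect_equal(gridLogLik(al1), gridLogLik(al2))
})

test_that("samples drawn from the reference recover their own age", {
    sim <- simulateCohort(cohortSpec(nSamples = 40, seed = 23))
    ref <- buildReference(sim$cohort, nGenes = 12)
    f <- expectedFreq(ref)
    set.seed(101)
    depth <- 1e6  # the cohort's typical library size; per-gene rates ~100
    for (ageIdx in c(2, 5, 9)) {
        preds <- replicate(200, {
            k <- rpois(nrow(f), f[, ageIdx] * depth)
            names(k) <- referenceGenes(ref)
            predictedAge(predictAge(k, ref, total = depth))
        })
        modal <- as.numeric(names(which.max(table(preds))))
        expect_equal(modal, defaultAgeGrid()[ageIdx])
    }
})

test_that("exact-age recovery is non-decreasing in sequencing depth", {
    sim <- simulateCohort(cohortSpec(nSamples = 40, seed = 29))
    ref <- buildReference(sim$cohort, nGenes = 12)
    f <- expectedFreq(ref)
    set.seed(131)
    rate <- vapply(c(1e3, 1e4, 1e5, 1e6), function(depth) {
        hits <- replicate(200, {
            ageIdx <- sample(10, 1)
            k <- rpois(nrow(f), f[, ageIdx] * depth)
            names(k) <- referenceGenes(ref)
            predictedAge(predictAge(k, ref, total = depth)) ==
                defaultAgeGrid()[ageIdx]
        })
        mean(hits)
    }, numeric(1))
    ## Monte-Carlo slack of 0.1 on 200 replicates per depth
    expect_true(all(diff(rate) >= -0.1))
})
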