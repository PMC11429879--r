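test_that("frequency normalization divides by sample totals", {
    m <- matrix(c(2, 3, 5, 0, 0, 7), 3, 2,
                dimnames = list(paste0("g", 1:3), c("a", "b")))
    f <- normalizeFrequencies(m)
    expect_equal(f[, "a"], c(g1 = 0.2, g2 = 0.3, g3 = 0.5))
    expect_equal(f[, "b"], c(g1 = 0, g2 = 0, g3 = 1))
    ## scale invariance: proportional columns normalize identically
    m2 <- cbind(x = c(1, 1, 2), y = c(10, 10, 20))
    rownames(m2) <- paste0("g", 1:3)
    f2 <- normalizeFrequencies(m2)
    expect_equal(unname(f2[, "x"]), unname(f2[, "y"]))
    ## every column sums to one
    set.seed(1)
    big <- matrix(rpois(5000, 20) + 1L, 100, 50,
                  dimnames = list(paste0("g", 1:100), paste0("s", 1:50)))
    expect_true(all(abs(colSums(normalizeFrequencies(big)) - 1) < 1e-12))
})

test_that("Spearman correlation matches the rank-then-Pearson oracle", {
    ages <- 1:10
    expect_equal(spearmanRho(0.001 * (1:10), ages), 1)
    expect_equal(spearmanRho(exp(1:10), ages), 1)    # monotone non-linear
    expect_true(is.na(spearmanRho(rep(0.004, 10), ages)))  # constant gene
    expect_error(spearmanRho(1:4, 1:5), "length")

    set.seed(7)
    for (i in 1:200) {
        n <- sample(3:50, 1)
        x <- sample(round(runif(n, 0, 8)))  # heavy ties
        y <- round(rnorm(n), 1)
        expect_equal(spearmanRho(x, y), spearmanOracle(x, y),
                     tolerance = 1e-12)
    }
})

test_that("LOWESS trend reproduces lines, constants, and smooths with tau", {
    ages <- rep(defaultAgeGrid(), each = 3L)
    lin <- 0.001 * ages
    fit <- fitLowessTrend(lin, ages, tau = 0.7)
    expect_equal(unname(fit), 0.001 * defaultAgeGrid(), tolerance = 1e-6)
    cst <- fitLowessTrend(rep(0.004, length(ages)), ages, tau = 0.7)
    expect_equal(unname(cst), rep(0.004, 10), tolerance = 1e-12)

    fx <- noisyLogisticFixture()
    wiggly <- fitLowessTrend(fx$freq, fx$ages, tau = 0.1)
    smooth <- fitLowessTrend(fx$freq, fx$ages, tau = 0.7)
    expect_gt(totalCurvature(wiggly), totalCurvature(smooth))

    expect_error(fitLowessTrend(lin, ages, tau = 0), "tau")
    expect_error(fitLowessTrend(lin, ages, tau = 1.5), "tau")
    expect_error(fitLowessTrend(c(1, 2), c(1, 3), tau = 0.5), "distinct")
})

test_that("grid evaluation interpolates, clamps, and floors", {
    expect_equal(evaluateOnGrid(c(0.002, 0.004), c(1, 3), grid = 2), 0.003)
    expect_equal(evaluateOnGrid(c(0.002, 0.004), c(1, 3), grid = 0.5), 0.002)
    expect_equal(evaluateOnGrid(c(-1e-5, 0.004), c(1, 3), grid = 1), 1e-9)
    expect_error(evaluateOnGrid(0.1, 1, grid = numeric(0)), "non-empty")
})

test_that("reference building selects planted signal and obeys contracts", {
    ## 5 clean monotone signal genes among 100 flat noise genes
    sim <- simulateCohort(cohortSpec(nSamples = 30, nSignalGenes = 5,
                                     nNoiseGenes = 100,
                                     baselineRange = c(1e-4, 1e-3),
                                     seed = 11))
    ref <- buildReference(sim$cohort, nGenes = 5)
    expect_setequal(referenceGenes(ref), sim$truth$signalGenes)

    ref12 <- buildReference(sim$cohort, nGenes = 12)
    expect_length(referenceGenes(ref12), 12)
    expect_identical(ageGrid(ref12), defaultAgeGrid())
    expect_true(all(expectedFreq(ref12) >= frequencyFloor(ref12)))
    expect_true(all(expectedFreq(ref12) <= 1))
    ## ranked by descending |rho|
    expect_true(all(diff(abs(geneCorrelations(ref12))) <= 0))

    ## asking for more genes than are rankable states both numbers
    cst <- matrix(5L, 4, 6, dimnames = list(paste0("g", 1:4),
                                            paste0("s", 1:6)))
    cc <- ClockCohort(cst, data.frame(sample = colnames(cst),
                                      age = rep(c(1, 9, 27), 2)))
    expect_error(buildReference(cc, nGenes = 2), "2.*0|0.*2")
})

test_that("reference building is invariant to input row/column order", {
    sim <- simulateCohort(cohortSpec(nSamples = 20, nSignalGenes = 10,
                                     nNoiseGenes = 40, seed = 13))
    m <- counts(sim$cohort)
    meta <- data.frame(sample = colnames(m), age = ages(sim$cohort))
    ref <- buildReference(ClockCohort(m, meta), nGenes = 8)
    set.seed(1)
    rs <- sample(nrow(m)); cs <- sample(ncol(m))
    shuffled <- ClockCohort(m[rs, cs], meta[cs, ])
    ref2 <- buildReference(shuffled, nGenes = 8)
    expect_identical(referenceGenes(ref2), referenceGenes(ref))
    expect_equal(expectedFreq(ref2), expectedFreq(ref))
})

test_that("increasing tau never increases total curvature of the fit", {
    fx <- noisyLogisticFixture()
    curv <- vapply(c(0.3, 0.5, 0.7, 0.9), function(tau)
        totalCurvature(fitLowessTrend(fx$freq, fx$ages, tau)), numeric(1))
    expect_true(all(diff(curv) <= 1e-15))
})
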