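#' Prediction accuracy metrics
#'
#' Mean absolute error (months), Pearson correlation, and R-squared in both
#' conventions: `r2_pearson` is the squared Pearson correlation (immune to
#' calibration shifts), `r2_cod` is the coefficient of determination
#' `1 - SS_res / SS_tot` (penalizes bias). Constant predictions make the
#' correlation undefined (`NA`); the MAE is still reported.
#'
#' @param trueAges,predictedAges equal-length numeric vectors, n >= 2;
#'   `trueAges` must not be constant.
#' @return named list: `mae`, `pearson_r`, `r2_pearson`, `r2_cod`.
#' @examples
#' computeMetrics(c(1, 3, 6), c(3, 5, 8))  # shifted: r = 1, r2_cod < 1
#' @export
computeMetrics <- function(trueAges, predictedAges) {
    if (length(trueAges) != length(predictedAges))
        stop("vectors must have equal length")
    if (length(trueAges) < 2L) stop("need at least 2 samples")
    if (sd(trueAges) == 0) stop("true ages are constant")
    res <- predictedAges - trueAges
    r <- if (sd(predictedAges) == 0) NA_real_ else cor(trueAges, predictedAges)
    list(mae = mean(abs(res)),
         pearson_r = r,
         r2_pearson = r^2,
         r2_cod = 1 - sum(res^2) / sum((trueAges - mean(trueAges))^2))
}

.assembleReport <- function(model, samples, age, predicted, failed, foldLog,
                            details = list()) {
    ok <- !is.na(predicted)
    pred <- data.frame(sample = samples[ok], age = age[ok],
                       predicted = predicted[ok],
                       residual = predicted[ok] - age[ok])
    metrics <- computeMetrics(pred$age, pred$predicted)
    if (length(failed))
        warning(length(failed), " fold(s) failed and were excluded from ",
                "metrics: ", paste(failed, collapse = ", "))
    new("ValidationReport", model = model, predictions = pred,
        metrics = metrics, foldLog = foldLog, failedFolds = failed,
        details = details)
}

#' Leave-one-out cross-validation of the Poisson clock
#'
#' For each sample, a reference is trained on all remaining samples
#' ([buildReference()]) and the held-out sample's age is predicted
#' ([predictAge()]). Folds that fail (e.g. an empty gene intersection) are
#' recorded and excluded from the metrics with a warning.
#'
#' @param cohort a [ClockCohort-class] with >= 4 samples.
#' @param tau,nGenes,grid,freqFloor passed to [buildReference()].
#' @return a [ValidationReport-class] with model label `"clock"`.
#' @export
loocvClock <- function(cohort, tau = 0.7, nGenes = 12L,
                       grid = defaultAgeGrid(), freqFloor = 1e-9) {
    stopifnot(is(cohort, "ClockCohort"))
    n <- ncol(cohort)
    if (n < 4L) stop("LOOCV needs at least 4 samples")
    samples <- colnames(cohort)
    age <- ages(cohort)
    m <- counts(cohort)
    tot <- colSums(m)
    predicted <- rep(NA_real_, n)
    failed <- character()
    foldLog <- data.frame(fold = seq_len(n), test_sample = samples,
                          n_train = n - 1L,
                          train_samples = vapply(seq_len(n), function(i)
                              paste(samples[-i], collapse = ";"),
                              character(1)))
    for (i in seq_len(n)) {
        pa <- tryCatch({
            ref <- buildReference(cohort[, -i], tau = tau, nGenes = nGenes,
                                  grid = grid, freqFloor = freqFloor)
            predictAge(m[, i], ref, total = tot[i], sampleId = samples[i])
        }, error = function(e) e)
        if (inherits(pa, "error")) failed <- c(failed, samples[i])
        else predicted[i] <- predictedAge(pa)
    }
    .assembleReport("clock", samples, age, predicted, failed, foldLog)
}

#' Leave-one-out cross-validation of the Elastic-Net baseline
#'
#' The linear baseline protocol: counts are `log(1 + x)` transformed and
#' each feature standardized to mean 0, sd 1 (fit within each training fold
#' and applied to the held-out sample). Hyperparameters are searched in two
#' passes over the full grid of `alphas` (overall penalty strength) times
#' `l1Ratios` (lasso/ridge mix): pass 1 scores every pair by LOOCV MAE at
#' iteration cap `maxitPass1`; pass 2 refits at the single best pair with
#' cap `maxitPass2` to produce the final predictions. Fitting is done with
#' \pkg{glmnet}, whose penalty `lambda * (alpha*|w|_1 + (1-alpha)/2*|w|_2^2)`
#' equals this parameterization with `lambda = alpha_overall` and
#' `alpha = l1_ratio`.
#'
#' @param cohort a [ClockCohort-class] with >= 4 samples and non-constant
#'   ages.
#' @param alphas penalty strengths (default the 8-value grid
#'   `1e-5 ... 100`).
#' @param l1Ratios lasso/ridge mixing values (default 0 to 1 in steps of
#'   0.1).
#' @param maxitPass1,maxitPass2 iteration caps for the two passes.
#' @return a [ValidationReport-class] with model label `"elasticnet"`;
#'   `reportDetails()` carries the evaluated grid (`grid`, one row per
#'   (alpha, l1_ratio) pair with its LOOCV MAE), the selected pair
#'   (`best`), and any pass-2 convergence warnings (`warnings`).
#' @export
loocvElasticNet <- function(cohort,
                            alphas = c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1,
                                       1, 10, 100),
                            l1Ratios = seq(0, 1, by = 0.1),
                            maxitPass1 = 1e4, maxitPass2 = 1e5) {
    stopifnot(is(cohort, "ClockCohort"))
    n <- ncol(cohort)
    if (n < 4L) stop("LOOCV needs at least 4 samples")
    age <- ages(cohort)
    if (sd(age) == 0) stop("ages are constant; regression is degenerate")
    samples <- colnames(cohort)
    X <- t(log1p(counts(cohort)))
    lamPath <- sort(unique(alphas), decreasing = TRUE)
    foldLog <- data.frame(fold = seq_len(n), test_sample = samples,
                          n_train = n - 1L,
                          train_samples = vapply(seq_len(n), function(i)
                              paste(samples[-i], collapse = ";"),
                              character(1)))
    scaleFold <- function(i) {
        Xtr <- X[-i, , drop = FALSE]
        mu <- colMeans(Xtr)
        sdv <- apply(Xtr, 2L, sd)
        sdv[sdv == 0 | !is.finite(sdv)] <- 1
        list(tr = sweep(sweep(Xtr, 2L, mu), 2L, sdv, "/"),
             te = rbind((X[i, ] - mu) / sdv))
    }
    ## pass 1: LOOCV predictions for every (alpha, l1_ratio) pair
    predArr <- array(NA_real_, c(n, length(alphas), length(l1Ratios)))
    for (i in seq_len(n)) {
        sc <- scaleFold(i)
        for (j in seq_along(l1Ratios)) {
            fit <- glmnet::glmnet(sc$tr, age[-i], alpha = l1Ratios[j],
                                  lambda = lamPath, standardize = FALSE,
                                  maxit = maxitPass1)
            predArr[i, , j] <- as.numeric(predict(fit, newx = sc$te,
                                                  s = alphas))
        }
    }
    gridDf <- expand.grid(alpha = alphas, l1_ratio = l1Ratios,
                          KEEP.OUT.ATTRS = FALSE)
    gridDf$mae <- mapply(function(a, l)
        mean(abs(predArr[, match(a, alphas), match(l, l1Ratios)] - age)),
        gridDf$alpha, gridDf$l1_ratio)
    bestIdx <- which.min(gridDf$mae)
    best <- gridDf[bestIdx, c("alpha", "l1_ratio")]
    ## pass 2: refit per fold at the selected pair with the larger cap
    convWarn <- character()
    predicted <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        sc <- scaleFold(i)
        fit <- withCallingHandlers(
            glmnet::glmnet(sc$tr, age[-i], alpha = best$l1_ratio,
                           lambda = lamPath, standardize = FALSE,
                           maxit = maxitPass2),
            warning = function(w) {
                convWarn <<- c(convWarn, conditionMessage(w))
                invokeRestart("muffleWarning")
            })
        predicted[i] <- as.numeric(predict(fit, newx = sc$te, s = best$alpha))
    }
    if (length(convWarn))
        warning("pass-2 convergence warning(s) recorded in the report")
    .assembleReport("elasticnet", samples, age, predicted, character(),
                    foldLog,
                    details = list(grid = gridDf, best = best,
                                   warnings = unique(convWarn)))
}

#' Residual-bias diagnostic
#'
#' Age acceleration (predicted minus chronological age) should not be
#' correlated with age; a biased clock over-predicts young and
#' under-predicts old samples (or vice versa). This fits a LOWESS trend of
#' the residuals against true age and reports the Spearman correlation of
#' residual with age as a scalar bias statistic (`NA` when residuals are
#' constant).
#'
#' @param report a [ValidationReport-class] with >= 4 prediction rows.
#' @param tau LOWESS neighborhood fraction (default 0.7).
#' @return list with `curve` (data.frame `age`, `residual_trend` at the
#'   distinct true ages) and `rho` (Spearman correlation).
#' @export
residualBias <- function(report, tau = 0.7) {
    stopifnot(is(report, "ValidationReport"))
    p <- predictionTable(report)
    if (nrow(p) < 4L) stop("need at least 4 prediction rows")
    fit <- fitLowessTrend(p$residual, p$age, tau)
    list(curve = data.frame(age = as.numeric(names(fit)),
                            residual_trend = unname(fit)),
         rho = spearmanRho(p$residual, p$age))
}

#' @describeIn ValidationReport per-sample predictions.
#' @export
setMethod("predictionTable", "ValidationReport", function(x) x@predictions)

#' @describeIn ValidationReport summary metrics list.
#' @export
setMethod("validationMetrics", "ValidationReport", function(x) x@metrics)

#' @describeIn ValidationReport the fold audit log.
#' @export
setMethod("foldLog", "ValidationReport", function(x) x@foldLog)

#' @describeIn ValidationReport sample ids of failed folds.
#' @export
setMethod("failedFolds", "ValidationReport", function(x) x@failedFolds)

#' @describeIn ValidationReport model label.
#' @export
setMethod("modelLabel", "ValidationReport", function(x) x@model)

#' @describeIn ValidationReport model-specific details list.
#' @export
setMethod("reportDetails", "ValidationReport", function(x) x@details)

setMethod("show", "ValidationReport", function(object) {
    m <- object@metrics
    cat("ValidationReport (", object@model, "): ",
        nrow(object@predictions), " samples", sep = "")
    if (length(object@failedFolds))
        cat(",", length(object@failedFolds), "failed fold(s)")
    cat("\n  MAE = ", sprintf("%.3f", m$mae), " months; Pearson r = ",
        sprintf("%.3f", m$pearson_r), "\n  R2 (squared Pearson) = ",
        sprintf("%.3f", m$r2_pearson), "; R2 (coeff. of determination) = ",
        sprintf("%.3f", m$r2_cod), "\n", sep = "")
    invisible(NULL)
})
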