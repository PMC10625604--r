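## Repeated-run robustness harness: the same cohort is re-generated with
## fresh batch-level perturbations and pushed through a frozen detection
## pipeline; the coefficient of variation of the pooled (net) sensitivity
## across runs quantifies batch robustness.

#' Fit a frozen CDAI detection pipeline on a peak-list cohort
#'
#' Convenience constructor used by [robustnessHarness()] and
#' [runPipeline()]: builds VLM boxes, aligns and trims the cohort, fits the
#' CDAI preprocessing recipe and trains the detection model, freezing every
#' state needed to score new peak lists.
#'
#' @param peaks,truth cohort tables as produced by [generateCohort()] (or
#'   read from disk).
#' @param reference metabolite reference table.
#' @param tolPpm VLM tolerance in ppm (default 5).
#' @param minPrevalence,k,regularization,balance recipe / trainer
#'   parameters.
#' @param nKeep optional PLS-DA reduction size (NULL = all features).
#' @return List of class `"cdaiPipeline"`: `boxes`, `reference`, `prep`,
#'   `featureIds`, `model`.
#' @export
fitCdaiPipeline <- function(peaks, truth, reference, tolPpm = 5,
                            minPrevalence = 0.1, k = 5, regularization = 1,
                            balance = TRUE, nKeep = NULL) {
    boxes <- buildBoxes(reference, tolPpm)
    se <- alignCohort(peaks, truth, boxes)
    se <- trimMatrix(se, reference)
    m <- sampleMatrix(se)
    yBin <- ifelse(classLabels(se) == "normal", "normal", "cancer")
    prep <- cdaiPrepFit(m, minPrevalence, k)
    trainMat <- prep$train
    if (!is.null(nKeep) && length(unique(yBin)) == 2) {
        pf <- plsdaFit(trainMat, yBin,
                       nComponents = min(2, min(dim(trainMat)) - 1))
        trainMat <- plsdaReduce(trainMat, pf, min(nKeep, ncol(trainMat)))
    }
    model <- trainCDAI(trainMat, yBin, regularization, balance)
    structure(list(boxes = boxes, reference = reference, prep = prep,
                   featureIds = model@featureIds, model = model),
              class = "cdaiPipeline")
}

#' Score a peak-list cohort through a frozen CDAI pipeline
#'
#' @param fit a `"cdaiPipeline"` from [fitCdaiPipeline()].
#' @param peaks,truth cohort tables for the samples to score.
#' @return data.frame: `sample_id`, `class_label`, `y_score`, `call`.
#' @export
predictCdaiPipeline <- function(fit, peaks, truth) {
    stopifnot(inherits(fit, "cdaiPipeline"))
    se <- alignCohort(peaks, truth, fit$boxes)
    se <- trimMatrix(se, fit$reference)
    m <- sampleMatrix(se)
    ## features unseen in this cohort enter as all-missing columns
    missingFeat <- setdiff(fit$prep$features, colnames(m))
    if (length(missingFeat)) {
        add <- matrix(NA_real_, nrow(m), length(missingFeat),
                      dimnames = list(rownames(m), missingFeat))
        m <- cbind(m, add)
    }
    proc <- cdaiPrepApply(fit$prep, m)
    score <- cdaiScore(fit$model, proc)
    data.frame(sample_id = rownames(m),
               class_label = classLabels(se),
               y_score = score,
               call = cdaiClassify(score, fit$model@threshold),
               stringsAsFactors = FALSE)
}

#' Repeated-run robustness of cancer detection
#'
#' Re-generates the same synthetic cohort `nRuns` times with fresh
#' batch-level intensity shifts (all other randomness fixed by the cohort
#' seed), scores each run through a frozen detection pipeline, and reports
#' per-run per-class detection sensitivity, the pooled (net) sensitivity
#' per run, and the coefficient of variation of net sensitivity across
#' runs. With `batchShiftSd = 0` every run is identical and the CV is
#' exactly 0.
#'
#' @param fit a frozen `"cdaiPipeline"` from [fitCdaiPipeline()].
#' @param reference,profiles generator inputs matching the pipeline.
#' @param classCounts named vector: samples per (cancer) class in the test
#'   cohort template.
#' @param nRuns number of repeated runs (default 10).
#' @param batchShiftSd batch-level log10 shift sd applied per run.
#' @param nBatches,dropoutRate,intensityNoiseSd,ppmErrorSd cohort template
#'   parameters (defaults as in [cohortConfig()]).
#' @param seed integer; `seed` fixes the cohort template, `seed + run`
#'   redraws the batch shifts.
#' @return List of class `"robustnessReport"`: `perRun` data.frame (run,
#'   class, tested, correct, sensitivity), `netSensitivity` per-run vector
#'   (percent), `cv` (sd/mean of net sensitivity).
#' @export
robustnessHarness <- function(fit, reference, profiles, classCounts,
                              nRuns = 10, batchShiftSd = 0.05, nBatches = 3,
                              dropoutRate = 0.1, intensityNoiseSd = 0.2,
                              ppmErrorSd = 5, seed = 1) {
    stopifnot(inherits(fit, "cdaiPipeline"))
    cfg <- cohortConfig(classCounts, nBatches = nBatches,
                        ppmErrorSd = ppmErrorSd,
                        batchShiftSd = batchShiftSd,
                        dropoutRate = dropoutRate,
                        intensityNoiseSd = intensityNoiseSd, seed = seed)
    perRun <- list()
    net <- numeric(nRuns)
    for (r in seq_len(nRuns)) {
        cohort <- generateCohort(reference, profiles, cfg,
                                 batchSeed = seed + r)
        res <- predictCdaiPipeline(fit, cohort$peaks, cohort$truth)
        isCancer <- res$class_label != "normal"
        correct <- res$call == "cancer" & isCancer
        tab <- do.call(rbind, lapply(unique(res$class_label[isCancer]),
                                     function(cl) {
            idx <- res$class_label == cl
            data.frame(run = r, class = cl, tested = sum(idx),
                       correct = sum(correct[idx]),
                       sensitivity = 100 * mean(correct[idx]))
        }))
        perRun[[r]] <- tab
        net[r] <- 100 * sum(correct) / sum(isCancer)
    }
    cv <- if (mean(net) == 0) NA_real_ else sd(net) / mean(net)
    structure(list(perRun = do.call(rbind, perRun), netSensitivity = net,
                   cv = cv), class = "robustnessReport")
}

#' @export
print.robustnessReport <- function(x, ...) {
    cat(sprintf("Robustness over %d runs: net sensitivity %s%%, CV = %.4g\n",
                length(x$netSensitivity),
                paste(formatPct(x$netSensitivity), collapse = ", "), x$cv))
    invisible(x)
}
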