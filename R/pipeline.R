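## End-to-end orchestration: simulate (optional) -> align -> preprocess ->
## CDAI -> route positives -> TOOAI -> evaluate, with a manifest recording
## versions, seeds and parameters. The tier-2 input set is exactly the
## tier-1 positive set: a sample the detection tier calls normal never
## reaches the tissue-of-origin tier.

#' Build a pipeline configuration
#'
#' Returns the default configuration (every stage parameter defaulted as
#' documented on the stage functions), with `...` overriding nested entries
#' by name. The configuration round-trips losslessly through
#' [writePipelineConfig()] / [readPipelineConfig()].
#'
#' @param ... named overrides merged over the defaults (nested lists are
#'   merged recursively).
#' @return List of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(...) {
    def <- list(
        seed = 1L,
        outDir = "mced-run",
        simulate = list(
            enabled = TRUE,
            nMetabolites = 200L,
            massLow = 66.7, massHigh = 1000,
            samplesPerClass = c(normal = 20, breast = 20, endometrial = 20),
            nAffected = 30L, effectSize = 0.5,
            nBatches = 3L, ppmErrorSd = 5, batchShiftSd = 0.05,
            dropoutRate = 0.1, intensityNoiseSd = 0.2),
        inputs = list(peaks = NULL, truth = NULL, reference = NULL),
        align = list(tolPpm = 5),
        preprocess = list(minPrevalence = 0.1, k = 5L),
        split = list(fraction = 0.5),
        cdai = list(regularization = 1, balance = TRUE, threshold = 0,
                    nKeep = NULL),
        tooai = list(family = "max-margin", grid = 1))
    ov <- list(...)
    merge <- function(a, b) {
        for (nm in names(b)) {
            if (is.list(a[[nm]]) && is.list(b[[nm]]))
                a[[nm]] <- merge(a[[nm]], b[[nm]])
            else a[nm] <- list(b[[nm]])   # keeps explicit NULLs
        }
        a
    }
    structure(merge(def, ov), class = "pipelineConfig")
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param config a `"pipelineConfig"`.
#' @param path YAML file path.
#' @return `writePipelineConfig()`: `path`, invisibly;
#'   `readPipelineConfig()`: the `"pipelineConfig"`.
#' @export
writePipelineConfig <- function(config, path) {
    raw <- unclass(config)
    ## named vectors survive YAML only as maps
    raw$simulate$samplesPerClass <- as.list(raw$simulate$samplesPerClass)
    yaml::write_yaml(raw, path, precision = 15)
    invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    if (!is.null(raw$simulate$samplesPerClass))
        raw$simulate$samplesPerClass <- unlist(raw$simulate$samplesPerClass)
    do.call(pipelineConfig, raw)
}

.stage <- function(name, verbose, expr) {
    if (verbose) message(sprintf("[%s] ...", name))
    tryCatch(expr, error = function(e)
        stop(sprintf("pipeline stage '%s' failed: %s", name,
                     conditionMessage(e)), call. = FALSE))
}

#' Run the full tiered detection pipeline
#'
#' Executes simulate (optional) -> align -> split -> CDAI preprocessing and
#' training -> scoring and thresholding of the test half -> routing of
#' CDAI-positive samples into the TOOAI tier -> TOOAI training and top-2
#' prediction -> evaluation. Every artifact is written as delimited text
#' under `config$outDir` together with a `manifest.yaml` recording package
#' version, seeds, parameters and per-stage sample/feature counts. Rerunning
#' with an identical configuration reproduces the outputs byte for byte.
#'
#' @param config a `"pipelineConfig"` from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @param verbose emit per-stage progress messages (default TRUE).
#' @return Invisibly, a list with the run artifacts (`reference`, `cohort`,
#'   `experiment`, `cdai`, `tooai`, `metrics`, `outDir`, `manifest`).
#' @export
runPipeline <- function(config = pipelineConfig(), verbose = TRUE) {
    stopifnot(inherits(config, "pipelineConfig"))
    outDir <- config$outDir
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(package = "metamced",
                     version = as.character(packageVersion("metamced")),
                     seed = config$seed, stages = list())

    ## ---- inputs ----
    if (isTRUE(config$simulate$enabled)) {
        sim <- config$simulate
        dat <- .stage("simulate", verbose, {
            ref <- generateReference(sim$nMetabolites, sim$massLow,
                                     sim$massHigh, seed = config$seed)
            prof <- makeClassProfiles(ref, names(sim$samplesPerClass),
                                      nAffected = sim$nAffected,
                                      effectSize = sim$effectSize,
                                      seed = config$seed)
            cfg <- cohortConfig(sim$samplesPerClass, nBatches = sim$nBatches,
                                ppmErrorSd = sim$ppmErrorSd,
                                batchShiftSd = sim$batchShiftSd,
                                dropoutRate = sim$dropoutRate,
                                intensityNoiseSd = sim$intensityNoiseSd,
                                scanRange = c(sim$massLow, sim$massHigh),
                                seed = config$seed)
            cohort <- generateCohort(ref, prof, cfg)
            writeTable(ref, file.path(outDir, "reference.tsv"))
            writeTable(cohort$peaks, file.path(outDir, "peaks.tsv"))
            writeTable(cohort$truth, file.path(outDir, "truth.tsv"))
            list(reference = ref, peaks = cohort$peaks,
                 truth = cohort$truth)
        })
    } else {
        dat <- .stage("load-inputs", verbose, {
            list(reference = readTable(config$inputs$reference),
                 peaks = readTable(config$inputs$peaks),
                 truth = readTable(config$inputs$truth))
        })
    }
    manifest$stages$inputs <- list(
        samples = nrow(dat$truth), peaks = nrow(dat$peaks),
        reference_metabolites = nrow(dat$reference))

    ## ---- align ----
    alignRes <- .stage("align", verbose, {
        boxes <- buildBoxes(dat$reference, config$align$tolPpm)
        se0 <- alignCohort(dat$peaks, dat$truth, boxes)
        se1 <- trimMatrix(se0, dat$reference)
        writeMCED(se1, file.path(outDir, "aligned"))
        list(se = se1, before = nrow(se0), boxes = boxes)
    })
    se <- alignRes$se
    manifest$stages$align <- list(
        tol_ppm = config$align$tolPpm,
        features_before_trim = alignRes$before,
        features_after_trim = nrow(se),
        overlapping_boxes = nrow(boxOverlaps(alignRes$boxes)))

    ## ---- split ----
    labels <- classLabels(se)
    withr_seed(config$seed)
    tr <- logical(ncol(se))
    for (cl in unique(labels)) {
        idx <- which(labels == cl)
        nTr <- max(1, min(length(idx) - 1,
                          round(config$split$fraction * length(idx))))
        tr[idx[sample.int(length(idx), nTr)]] <- TRUE
    }
    manifest$stages$split <- list(train = sum(tr), test = sum(!tr))

    m <- sampleMatrix(se)
    yBin <- ifelse(labels == "normal", "normal", "cancer")

    ## ---- CDAI tier ----
    cdai <- .stage("cdai", verbose, {
        prep <- cdaiPrepFit(m[tr, , drop = FALSE],
                            config$preprocess$minPrevalence,
                            config$preprocess$k)
        trainMat <- prep$train
        if (!is.null(config$cdai$nKeep)) {
            pf <- plsdaFit(trainMat, yBin[tr],
                           nComponents = min(2, min(dim(trainMat)) - 1))
            trainMat <- plsdaReduce(trainMat, pf,
                                    min(config$cdai$nKeep, ncol(trainMat)))
        }
        model <- trainCDAI(trainMat, yBin[tr], config$cdai$regularization,
                           config$cdai$balance, config$cdai$threshold)
        writeCDAIModel(model, file.path(outDir, "cdai_model.tsv"))
        testMat <- cdaiPrepApply(prep, m[!tr, , drop = FALSE])
        score <- cdaiScore(model, testMat)
        call <- cdaiClassify(score, model@threshold)
        scores <- data.frame(sample_id = rownames(testMat),
                             class_label = labels[!tr],
                             y_score = score, cdai_call = call,
                             stringsAsFactors = FALSE)
        writeTable(scores, file.path(outDir, "cdai_scores.tsv"))
        cc <- confusionCounts(call, yBin[!tr])
        metrics <- list(sensitivity = sensitivity(cc),
                        specificity = specificity(cc),
                        accuracy = accuracy(cc),
                        roc_auc = rocAuc(score, yBin[!tr]))
        list(prep = prep, model = model, scores = scores, metrics = metrics)
    })
    manifest$stages$cdai <- c(
        list(features = length(cdai$model@featureIds)),
        lapply(cdai$metrics, function(v) round(v, 4)))

    ## ---- routing: tier 2 sees exactly the tier-1 positives ----
    routed <- cdai$scores$sample_id[cdai$scores$cdai_call == "cancer"]
    manifest$stages$routing <- list(cdai_positive = length(routed),
                                    cdai_negative = sum(!tr) - length(routed))

    ## ---- TOOAI tier ----
    runTooai <- function() {
        trCancer <- tr & yBin == "cancer"
        if (length(unique(labels[trCancer])) < 2 || length(routed) == 0)
            return(NULL)
        prep <- tooaiPrepFit(m[trCancer, , drop = FALSE], labels[trCancer],
                             config$preprocess$minPrevalence,
                             config$preprocess$k)
        model <- trainTOOAI(prep$train, labels[trCancer],
                            family = config$tooai$family,
                            grid = config$tooai$grid, seed = config$seed)
        writeTOOAIModel(model, file.path(outDir, "tooai_model"))
        testMat <- tooaiPrepApply(prep, m[routed, , drop = FALSE])
        pred <- tooaiPredict(model, testMat)
        report <- data.frame(sample_id = routed,
                             class_label = labels[match(routed,
                                                        colnames(se))],
                             y_score = cdai$scores$y_score[
                                 match(routed, cdai$scores$sample_id)],
                             cdai_call = "cancer",
                             pred$scores,
                             top1 = pred$top1, top2 = pred$top2[, 2],
                             check.names = FALSE, stringsAsFactors = FALSE)
        writeTable(report, file.path(outDir, "tooai_predictions.tsv"))
        ## accuracy evaluated on routed samples whose truth is a cancer class
        isCancer <- report$class_label %in% model@classLabels
        acc <- NULL
        if (any(isCancer)) {
            sub <- structure(list(
                scores = pred$scores[isCancer, , drop = FALSE],
                top1 = pred$top1[isCancer],
                top2 = pred$top2[isCancer, , drop = FALSE],
                classLabels = model@classLabels), class = "tooaiPrediction")
            acc <- doubleClassAccuracy(sub, report$class_label[isCancer])
            cm <- doubleClassConfusion(sub, report$class_label[isCancer])
            writeTable(data.frame(truth = rownames(cm), cm,
                                  check.names = FALSE),
                       file.path(outDir, "tooai_confusion.tsv"))
            writeTable(acc$perClass, file.path(outDir,
                                               "tooai_per_class.tsv"))
        }
        list(prep = prep, model = model, predictions = pred,
             report = report, accuracy = acc)
    }
    tooai <- .stage("tooai", verbose, runTooai())
    manifest$stages$tooai <- if (is.null(tooai)) {
        list(skipped = "need >= 2 cancer classes and >= 1 routed sample")
    } else {
        acc <- tooai$accuracy
        list(classes = length(tooai$model@classLabels),
             routed = length(routed),
             single_class_accuracy = if (!is.null(acc)) round(acc$top1, 4),
             double_class_accuracy = if (!is.null(acc)) round(acc$overall, 4))
    }

    yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
    if (verbose) message("[done] artifacts in ", outDir)
    invisible(list(reference = dat$reference,
                   cohort = list(peaks = dat$peaks, truth = dat$truth),
                   experiment = se, train = tr, cdai = cdai, tooai = tooai,
                   metrics = c(cdai$metrics,
                               if (!is.null(tooai$accuracy))
                                   list(tooai_single = tooai$accuracy$top1,
                                        tooai_double = tooai$accuracy$overall)),
                   outDir = outDir, manifest = manifest))
}
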