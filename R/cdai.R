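## Tier 1: the cancer-detection linear score. An L2-regularized logistic
## regression supplies the affine score y = x0 + sum_i x_i * I_i; decisions
## apply a threshold of 0, and performance is summarized over repeated
## stratified random train/test splits with percentile 95% CIs.

.checkBinary <- function(labels) {
    u <- sort(unique(as.character(labels)))
    if (!identical(u, c("cancer", "normal")))
        stop("labels must contain both 'cancer' and 'normal'")
    factor(labels, levels = c("normal", "cancer"))
}

#' Train the CDAI binary scorer
#'
#' Ridge-penalized logistic regression of cancer vs normal; with
#' `balance = TRUE` (the default) per-sample weights are inversely
#' proportional to class frequency, countering the cancer:normal imbalance.
#' The fitted intercept and coefficients are exposed as a [CDAIModel-class]
#' whose linear predictor is exactly the y_score.
#'
#' @param x samples x features training matrix (complete) or
#'   [MCEDExperiment-class].
#' @param labels per-sample `"cancer"` / `"normal"`.
#' @param regularization ridge penalty lambda (> 0; default 1).
#' @param balance logical; apply inverse-frequency class weights.
#' @param threshold decision threshold on the score (default 0).
#' @return A [CDAIModel-class].
#' @export
trainCDAI <- function(x, labels, regularization = 1, balance = TRUE,
                      threshold = 0) {
    h <- .asSampleMat(x)
    m <- h$mat
    if (is(x, "MCEDExperiment") && missing(labels))
        labels <- ifelse(classLabels(x) == "normal", "normal", "cancer")
    y <- .checkBinary(labels)
    if (regularization <= 0) stop("regularization must be > 0")
    if (anyNA(m)) stop("training matrix must be imputed (no missing cells)")
    w <- rep(1, length(y))
    if (balance) {
        tab <- table(y)
        w <- as.numeric(length(y) / (2 * tab[y]))
    }
    fit <- glmnet::glmnet(m, y, family = "binomial", alpha = 0,
                          lambda = regularization, weights = w,
                          standardize = TRUE, thresh = 1e-11, maxit = 1e6)
    beta <- setNames(as.numeric(fit$beta), rownames(fit$beta))
    methods::new("CDAIModel",
                 intercept = as.numeric(fit$a0),
                 coefficients = beta,
                 featureIds = colnames(m),
                 threshold = threshold)
}

#' Compute the CDAI y_score
#'
#' Returns `x0 + sum_i x_i * I_i` exactly. Missing intensities enter as 0
#' (the training mean after standardization, per the preprocessing
#' contract).
#'
#' @param model A [CDAIModel-class].
#' @param x named numeric vector for one sample, or samples x features
#'   matrix; features must align with `model@featureIds` (named inputs are
#'   reordered; unnamed inputs must already align and match in length).
#' @return Numeric score(s).
#' @export
cdaiScore <- function(model, x) {
    stopifnot(is(model, "CDAIModel"))
    if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                     dimnames = list(NULL, names(x)))
    if (!is.null(colnames(x))) {
        if (!all(model@featureIds %in% colnames(x)))
            stop("sample features do not cover the model's feature ids")
        x <- x[, model@featureIds, drop = FALSE]
    } else if (ncol(x) != length(model@featureIds)) {
        stop("unnamed input must match the model's feature count")
    }
    x[is.na(x)] <- 0
    as.numeric(model@intercept + x %*% model@coefficients)
}

#' Threshold a CDAI score into a class call
#'
#' Scores at or above the threshold are called `"cancer"`, below it
#' `"normal"` (the measure-zero exact tie goes to cancer: a screening
#' context favours sensitivity).
#'
#' @param score numeric score(s) from [cdaiScore()].
#' @param threshold decision threshold (default 0).
#' @return Character vector of `"cancer"` / `"normal"` calls.
#' @export
cdaiClassify <- function(score, threshold = 0) {
    if (any(!is.finite(score))) stop("scores must be finite")
    ifelse(score >= threshold, "cancer", "normal")
}

#' Repeated random-split cross-validation of the CDAI tier
#'
#' Per split: a stratified-by-class random partition (fraction
#' `splitFraction` to training), the full CDAI preprocessing recipe refit on
#' the training half only, model training, scoring of the held-out half, and
#' confusion-count metrics. Summaries are means with percentile 95%
#' confidence intervals. A split that leaves a class absent from either
#' partition is resampled (with a message).
#'
#' @param x samples x features matrix (raw aligned intensities, NA =
#'   missing) or [MCEDExperiment-class].
#' @param labels per-sample `"cancer"` / `"normal"` (derived from
#'   `class_label != "normal"` for an MCEDExperiment).
#' @param nSplits number of random splits (study scale: 1000).
#' @param splitFraction fraction assigned to training (default 0.5,
#'   mirroring the half-and-half study partition).
#' @param seed integer seed driving all splits.
#' @param minPrevalence,k,regularization,balance passed to the recipe and
#'   trainer.
#' @param nKeep optional PLS-DA reduction size applied after preprocessing
#'   (NULL = keep all features).
#' @return List of class `"cdaiCV"`: `perSplit` data.frame (sensitivity,
#'   specificity, accuracy per split, in percent) and `summary` data.frame
#'   (mean, ci_lower, ci_upper per metric).
#' @export
crossValidateCDAI <- function(x, labels, nSplits = 1000, splitFraction = 0.5,
                              seed = 1, minPrevalence = 0.1, k = 5,
                              regularization = 1, balance = TRUE,
                              nKeep = NULL) {
    h <- .asSampleMat(x)
    m <- h$mat
    if (is(x, "MCEDExperiment") && missing(labels))
        labels <- ifelse(classLabels(x) == "normal", "normal", "cancer")
    y <- as.character(labels)
    if (nSplits < 1) stop("nSplits must be >= 1")
    withr_seed(seed)
    res <- matrix(NA_real_, nSplits, 3,
                  dimnames = list(NULL, c("sensitivity", "specificity",
                                          "accuracy")))
    for (s in seq_len(nSplits)) {
        attempt <- 0
        repeat {
            attempt <- attempt + 1
            if (attempt > 100)
                stop("cannot form a split with both classes in both partitions")
            tr <- logical(length(y))
            for (cl in unique(y)) {
                idx <- which(y == cl)
                nTr <- min(length(idx) - 1, max(1, round(splitFraction * length(idx))))
                if (nTr > 0) tr[idx[sample.int(length(idx), nTr)]] <- TRUE
            }
            if (length(unique(y[tr])) == 2 && length(unique(y[!tr])) == 2)
                break
            message("split ", s, ": class absent from a partition; resampling")
        }
        prep <- cdaiPrepFit(m[tr, , drop = FALSE], minPrevalence, k)
        trainMat <- prep$train
        if (!is.null(nKeep)) {
            pf <- plsdaFit(trainMat, y[tr],
                           nComponents = min(2, min(dim(trainMat)) - 1))
            trainMat <- plsdaReduce(trainMat, pf,
                                    min(nKeep, ncol(trainMat)))
        }
        model <- trainCDAI(trainMat, y[tr], regularization, balance)
        testMat <- cdaiPrepApply(prep, m[!tr, , drop = FALSE])
        calls <- cdaiClassify(cdaiScore(model, testMat), model@threshold)
        cc <- confusionCounts(calls, y[!tr])
        res[s, ] <- c(sensitivity(cc), specificity(cc), accuracy(cc))
    }
    summ <- data.frame(
        metric = colnames(res),
        mean = colMeans(res),
        ci_lower = apply(res, 2, quantile, 0.025, names = FALSE),
        ci_upper = apply(res, 2, quantile, 0.975, names = FALSE),
        row.names = NULL)
    structure(list(perSplit = as.data.frame(res), summary = summ,
                   nSplits = nSplits), class = "cdaiCV")
}

#' @export
print.cdaiCV <- function(x, ...) {
    cat(sprintf("CDAI cross-validation over %d random splits (95%% percentile CI):\n",
                x$nSplits))
    s <- x$summary
    for (i in seq_len(nrow(s)))
        cat(sprintf("  %-12s %5.1f (%.1f-%.1f)\n", s$metric[i], s$mean[i],
                    s$ci_lower[i], s$ci_upper[i]))
    invisible(x)
}
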