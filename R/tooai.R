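## Tier 2: tissue-of-origin scoring. One-vs-rest linear scorers (linear SVM
## by default, ridge logistic as an alternative family); each class emits a
## sigmoid-mapped linear score, and decisions use the top-1 / top-2 scored
## classes. Scores are deliberately NOT renormalized across classes.

.ovrLinearSVM <- function(m, yBin, cost) {
    wts <- c("FALSE" = 1, "TRUE" = 1)
    tab <- table(yBin)
    wts <- length(yBin) / (2 * tab)
    names(wts) <- names(tab)
    fit <- e1071::svm(m, yBin, kernel = "linear", cost = cost, scale = FALSE,
                      class.weights = wts)
    w <- drop(t(fit$coefs) %*% fit$SV)
    b <- -fit$rho
    dv <- drop(m %*% w) + b
    ## orient so the positive (this-class) side has the larger decision value
    if (mean(dv[yBin == "TRUE"]) < mean(dv[yBin == "FALSE"])) {
        w <- -w; b <- -b
    }
    list(w = w, b = b)
}

.ovrRidgeLogistic <- function(m, yBin, lambda) {
    fit <- glmnet::glmnet(m, yBin, family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE,
                          thresh = 1e-12, maxit = 1e6)
    list(w = setNames(as.numeric(fit$beta), rownames(fit$beta)),
         b = as.numeric(fit$a0))
}

.fitTOOAI <- function(m, labels, classLabels, family, hyper) {
    K <- length(classLabels)
    W <- matrix(0, K, ncol(m), dimnames = list(classLabels, colnames(m)))
    b <- setNames(numeric(K), classLabels)
    for (cl in classLabels) {
        yBin <- factor(labels == cl, levels = c(FALSE, TRUE))
        fit <- if (family == "max-margin") .ovrLinearSVM(m, yBin, hyper)
               else .ovrRidgeLogistic(m, yBin, hyper)
        W[cl, ] <- fit$w
        b[cl] <- fit$b
    }
    methods::new("TOOAIModel", classLabels = classLabels, intercepts = b,
                 weights = W, featureIds = colnames(m), family = family)
}

#' Train the TOOAI multiclass scorer
#'
#' Fits one linear one-vs-rest scorer per cancer class. The default
#' `"max-margin"` family uses a linear support-vector machine per class
#' (with inverse-frequency class weights); `"logistic-ovr"` uses ridge
#' logistic regression. When the hyperparameter grid has more than one
#' value, the value with the best held-out single-class (top-1) accuracy on
#' an internal stratified 75/25 split is selected, then the model is refit
#' on all training samples.
#'
#' @param x samples x features training matrix (complete / imputed) or
#'   [MCEDExperiment-class].
#' @param labels cancer class label per training sample.
#' @param family `"max-margin"` (linear SVM, the default) or
#'   `"logistic-ovr"`.
#' @param grid numeric vector of candidate hyperparameters (SVM cost or
#'   ridge lambda); default `c(0.1, 1, 10)` for SVM.
#' @param classLabels optional complete label set; training labels missing
#'   from it raise an error listing the absentees.
#' @param seed seed for the internal selection split.
#' @return A [TOOAIModel-class].
#' @export
trainTOOAI <- function(x, labels, family = c("max-margin", "logistic-ovr"),
                       grid = NULL, classLabels = NULL, seed = 1) {
    family <- match.arg(family)
    h <- .asSampleMat(x)
    m <- h$mat
    if (is(x, "MCEDExperiment") && missing(labels)) labels <- classLabels(x)
    labels <- as.character(labels)
    if (anyNA(m)) stop("training matrix must be imputed (no missing cells)")
    if (is.null(classLabels)) classLabels <- sort(unique(labels))
    absent <- setdiff(classLabels, unique(labels))
    if (length(absent))
        stop("class(es) absent from training: ", paste(absent, collapse = ", "))
    if (length(classLabels) < 2) stop("need >= 2 classes")
    if (is.null(grid))
        grid <- if (family == "max-margin") c(0.1, 1, 10) else c(0.001, 0.01, 0.1)
    best <- grid[1]
    if (length(grid) > 1) {
        withr_seed(seed)
        tr <- logical(length(labels))
        for (cl in classLabels) {
            idx <- which(labels == cl)
            nTr <- max(1, min(length(idx) - 1, round(0.75 * length(idx))))
            tr[idx[sample.int(length(idx), nTr)]] <- TRUE
        }
        if (length(unique(labels[!tr])) < 2) {
            tr[] <- TRUE          # degenerate toy: select on training fit
        }
        hold <- if (all(tr)) which(tr) else which(!tr)
        acc <- vapply(grid, function(g) {
            fit <- .fitTOOAI(m[tr, , drop = FALSE], labels[tr], classLabels,
                             family, g)
            pred <- tooaiPredict(fit, m[hold, , drop = FALSE])
            mean(pred$top1 == labels[hold])
        }, numeric(1))
        best <- grid[which.max(acc)]   # ties resolve to the smaller value
    }
    .fitTOOAI(m, labels, classLabels, family, best)
}

#' Predict tissue-of-origin class probabilities
#'
#' Per class k the score is `sigmoid(a_k + w_k . I)`; scores lie in (0,1)
#' but are not renormalized across classes. `top1` is the highest-scoring
#' class and `top2` the two highest in descending order, ties broken
#' lexicographically. Missing intensities enter as 0 (the training mean
#' after standardization: the tissue-of-origin test set is deliberately
#' non-imputed).
#'
#' @param model A [TOOAIModel-class].
#' @param x named numeric vector (one sample) or samples x features matrix
#'   aligned to the model's features.
#' @return List of class `"tooaiPrediction"`: `scores` (samples x classes
#'   matrix), `top1` (character), `top2` (samples x 2 character matrix).
#' @export
tooaiPredict <- function(model, x) {
    stopifnot(is(model, "TOOAIModel"))
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
    z <- sweep(x %*% t(model@weights), 2, model@intercepts, "+")
    scores <- plogis(z)
    colnames(scores) <- model@classLabels
    ## rank by descending score with lexicographic tie-break on the label
    pickTop <- function(v) {
        ord <- order(-v, model@classLabels)
        model@classLabels[ord[1:2]]
    }
    tops <- t(apply(scores, 1, pickTop))
    structure(list(scores = scores, top1 = tops[, 1],
                   top2 = tops, classLabels = model@classLabels),
              class = "tooaiPrediction")
}

#' @export
print.tooaiPrediction <- function(x, ...) {
    cat(sprintf("TOOAI predictions for %d sample(s), %d classes\n",
                nrow(x$scores), ncol(x$scores)))
    invisible(x)
}

.checkTruths <- function(predictions, truths) {
    stopifnot(inherits(predictions, "tooaiPrediction"))
    truths <- as.character(truths)
    if (length(truths) != nrow(predictions$scores))
        stop("predictions and truths must have equal length")
    bad <- setdiff(unique(truths), predictions$classLabels)
    if (length(bad))
        stop("unknown truth label(s): ", paste(bad, collapse = ", "))
    truths
}

#' Double-class (top-2) prediction accuracy
#'
#' Fraction of samples whose true class lies within the two highest-scoring
#' predictions, as a percentage, with a per-class breakdown. Always at least
#' the single-class (top-1) accuracy.
#'
#' @param predictions a `"tooaiPrediction"` from [tooaiPredict()].
#' @param truths true class label per sample.
#' @return List: `overall` (percentage), `top1` (top-1 percentage),
#'   `perClass` data.frame (`class`, `tested`, `correct`, `sensitivity`).
#' @export
doubleClassAccuracy <- function(predictions, truths) {
    truths <- .checkTruths(predictions, truths)
    hit2 <- truths == predictions$top2[, 1] | truths == predictions$top2[, 2]
    hit1 <- truths == predictions$top1
    perClass <- do.call(rbind, lapply(sort(unique(truths)), function(cl) {
        idx <- truths == cl
        data.frame(class = cl, tested = sum(idx), correct = sum(hit2[idx]),
                   sensitivity = 100 * mean(hit2[idx]))
    }))
    list(overall = 100 * mean(hit2), top1 = 100 * mean(hit1),
         perClass = perClass)
}

#' Double-class confusion matrix
#'
#' Samples whose true class is within the top two predictions are credited
#' to the diagonal; all others are counted at (truth, top-1). Row sums equal
#' the per-class sample counts.
#'
#' @inheritParams doubleClassAccuracy
#' @return Integer matrix, true classes x predicted classes.
#' @export
doubleClassConfusion <- function(predictions, truths) {
    truths <- .checkTruths(predictions, truths)
    K <- predictions$classLabels
    cm <- matrix(0L, length(K), length(K), dimnames = list(truth = K,
                                                           predicted = K))
    hit2 <- truths == predictions$top2[, 1] | truths == predictions$top2[, 2]
    target <- ifelse(hit2, truths, predictions$top1)
    for (i in seq_along(truths))
        cm[truths[i], target[i]] <- cm[truths[i], target[i]] + 1L
    cm
}

#' Repeated random-split cross-validation of the TOOAI tier
#'
#' Per split: a stratified partition of the cancer samples, the TOOAI
#' preprocessing recipe refit on the training half (selective per-class
#' imputation; test half left non-imputed), model training, and top-1 /
#' top-2 accuracies on the held-out half. Study scale uses 100 splits.
#'
#' @param x samples x features matrix of raw aligned intensities (NA =
#'   missing) or [MCEDExperiment-class]; cancer samples only.
#' @param labels cancer class per sample.
#' @param nSplits number of random splits (default 100).
#' @param splitFraction fraction assigned to training (default 0.5).
#' @param seed integer seed.
#' @param minPrevalence,k recipe parameters.
#' @param family,grid passed to [trainTOOAI()].
#' @return List of class `"tooaiCV"`: `perSplit` (top-1 and top-2 accuracy
#'   percentages per split) and `summary` (mean and percentile 95% CI).
#' @export
crossValidateTOOAI <- function(x, labels, nSplits = 100, splitFraction = 0.5,
                               seed = 1, minPrevalence = 0.1, k = 5,
                               family = "max-margin", grid = 1) {
    h <- .asSampleMat(x)
    m <- h$mat
    if (is(x, "MCEDExperiment") && missing(labels)) labels <- classLabels(x)
    labels <- as.character(labels)
    withr_seed(seed)
    res <- matrix(NA_real_, nSplits, 2,
                  dimnames = list(NULL, c("top1", "top2")))
    for (s in seq_len(nSplits)) {
        tr <- logical(length(labels))
        for (cl in unique(labels)) {
            idx <- which(labels == cl)
            nTr <- max(1, min(length(idx) - 1,
                              round(splitFraction * length(idx))))
            tr[idx[sample.int(length(idx), nTr)]] <- TRUE
        }
        prep <- tooaiPrepFit(m[tr, , drop = FALSE], labels[tr],
                             minPrevalence, k)
        model <- trainTOOAI(prep$train, labels[tr], family = family,
                            grid = grid, seed = seed + s)
        testMat <- tooaiPrepApply(prep, m[!tr, , drop = FALSE])
        pred <- tooaiPredict(model, testMat)
        acc <- doubleClassAccuracy(pred, labels[!tr])
        res[s, ] <- c(acc$top1, acc$overall)
    }
    summ <- data.frame(
        metric = colnames(res),
        mean = colMeans(res),
        ci_lower = apply(res, 2, quantile, 0.025, names = FALSE),
        ci_upper = apply(res, 2, quantile, 0.975, names = FALSE),
        row.names = NULL)
    structure(list(perSplit = as.data.frame(res), summary = summ,
                   nSplits = nSplits), class = "tooaiCV")
}

#' @export
print.tooaiCV <- function(x, ...) {
    cat(sprintf("TOOAI cross-validation over %d random splits (95%% percentile CI):\n",
                x$nSplits))
    s <- x$summary
    for (i in seq_len(nrow(s)))
        cat(sprintf("  %-6s accuracy %5.1f (%.1f-%.1f)\n", s$metric[i],
                    s$mean[i], s$ci_lower[i], s$ci_upper[i]))
    invisible(x)
}
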