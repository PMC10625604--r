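## PLS-DA feature reduction with R2/Q2 diagnostics. The latent-variable
## engine is mixOmics::plsda; this file adds the importance statistic used
## for reduction (sum of squared loading weights across components), the
## explained-variation R2 and the cross-validated predictive Q2.

.oneHot <- function(labels) {
    f <- factor(labels)
    Y <- matrix(0, length(f), nlevels(f),
                dimnames = list(NULL, levels(f)))
    Y[cbind(seq_along(f), as.integer(f))] <- 1
    Y
}

## stratified fold ids: each class spread as evenly as possible
.stratifiedFolds <- function(labels, nFolds, seed) {
    withr_seed(seed)
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- rep(seq_len(nFolds), length.out = length(idx))
    }
    fold
}

#' Fit PLS-DA and compute feature importance, R2 and Q2
#'
#' Partial least squares against one-hot class indicators. Per-feature
#' importance is the sum over components of the squared loading weights
#' (VIP-like); R2 is the fraction of indicator variance explained by the
#' training-set prediction; Q2 the cross-validated analogue
#' (`1 - PRESS/TSS` over stratified k-fold prediction).
#'
#' @param x samples x features matrix (no missing cells) or
#'   [MCEDExperiment-class].
#' @param labels class label per sample (>= 2 classes).
#' @param nComponents number of latent components (default 2; must be less
#'   than `min(samples, features)`).
#' @param nFolds folds for the Q2 cross-validation (default 5).
#' @param seed seed for the fold assignment.
#' @return List of class `"plsdaFit"`: `scores`, `loadings`, `importance`
#'   (named, >= 0), `R2`, `Q2`, `nComponents`, `classLevels`.
#' @export
plsdaFit <- function(x, labels, nComponents = 2, nFolds = 5, seed = 1) {
    h <- .asSampleMat(x)
    m <- h$mat
    if (is(x, "MCEDExperiment") && missing(labels)) labels <- classLabels(x)
    labels <- as.character(labels)
    if (length(unique(labels)) < 2) stop("PLS-DA requires >= 2 classes")
    if (nComponents >= min(dim(m)))
        stop("nComponents must be < min(samples, features)")
    if (anyNA(m)) stop("PLS-DA requires a complete (imputed) matrix")
    sds <- apply(m, 2, sd)
    if (all(sds == 0)) stop("degenerate matrix: all features constant")
    if (any(sds == 0)) {
        warning(sum(sds == 0), " constant feature(s) dropped for PLS-DA")
        m <- m[, sds > 0, drop = FALSE]
    }
    f <- factor(labels)
    fit <- mixOmics::plsda(m, f, ncomp = nComponents)
    W <- fit$loadings$X
    importance <- rowSums(W^2)
    names(importance) <- colnames(m)

    Y <- .oneHot(labels)
    pred <- predict(fit, m)$predict[, , nComponents, drop = TRUE]
    TSS <- sum(sweep(Y, 2, colMeans(Y))^2)
    R2 <- 1 - sum((Y - pred)^2) / TSS

    ## Q2 by stratified k-fold cross-validation
    nFolds <- min(nFolds, min(table(labels)))
    Q2 <- NA_real_
    if (nFolds >= 2) {
        fold <- .stratifiedFolds(labels, nFolds, seed)
        press <- 0; tss <- 0
        for (kf in seq_len(nFolds)) {
            tr <- fold != kf
            if (length(unique(labels[tr])) < 2) next
            mtr <- m[tr, , drop = FALSE]
            keep <- apply(mtr, 2, sd) > 0
            fitk <- mixOmics::plsda(mtr[, keep, drop = FALSE], f[tr],
                                    ncomp = min(nComponents,
                                                sum(tr) - 1, sum(keep) - 1))
            pk <- predict(fitk, m[!tr, keep, drop = FALSE])$predict
            pk <- pk[, , dim(pk)[3], drop = TRUE]
            if (is.null(dim(pk))) pk <- matrix(pk, nrow = sum(!tr))
            Yk <- .oneHot(labels)[!tr, colnames(Y)[colnames(Y) %in%
                                                   levels(f)], drop = FALSE]
            ## align predicted columns to indicator columns
            pk <- pk[, colnames(Yk), drop = FALSE]
            press <- press + sum((Yk - pk)^2)
            tss <- tss + sum(sweep(Yk, 2,
                                   colMeans(.oneHot(labels)[tr, , drop = FALSE]))^2)
        }
        Q2 <- 1 - press / tss
    }
    structure(list(scores = fit$variates$X, loadings = W,
                   importance = importance, R2 = R2, Q2 = Q2,
                   nComponents = nComponents, classLevels = levels(f)),
              class = "plsdaFit")
}

#' @export
print.plsdaFit <- function(x, ...) {
    cat(sprintf("PLS-DA fit: %d components, %d features\n",
                x$nComponents, length(x$importance)))
    cat(sprintf("  R2 = %.3f, Q2 = %.3f\n", x$R2, x$Q2))
    invisible(x)
}

#' Reduce a matrix to the top PLS-DA features
#'
#' Keeps the `nKeep` features with the largest PLS-DA importance, preserving
#' the original column order.
#'
#' @param x samples x features matrix or [MCEDExperiment-class].
#' @param fit a `"plsdaFit"` from [plsdaFit()].
#' @param nKeep number of features to keep (`1 <= nKeep <=` feature count;
#'   at study scale the detection model constrains this to 1000-5104).
#' @return Reduced object of the same type as `x`.
#' @export
plsdaReduce <- function(x, fit, nKeep) {
    stopifnot(inherits(fit, "plsdaFit"))
    h <- .asSampleMat(x)
    feats <- names(fit$importance)
    feats <- feats[feats %in% colnames(h$mat)]
    if (nKeep < 1 || nKeep > length(feats))
        stop("nKeep must lie in [1, ", length(feats), "]")
    top <- names(sort(fit$importance[feats], decreasing = TRUE))[seq_len(nKeep)]
    keep <- colnames(h$mat)[colnames(h$mat) %in% top]
    .restoreType(h$mat[, keep, drop = FALSE], h)
}
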