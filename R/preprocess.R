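## Preprocessing stack: prevalence filtering, reference-based quantile
## normalization (applicable one sample at a time), log10 transform,
## standard scaling, and KNN imputation with uniform / selective policies.
##
## All statistical functions here operate on samples x features numeric
## matrices with NA marking missing cells; an MCEDExperiment may be passed
## wherever a matrix is accepted and is returned in kind.

.asSampleMat <- function(x) {
    if (is(x, "MCEDExperiment"))
        list(mat = sampleMatrix(x), se = x)
    else if (is.matrix(x))
        list(mat = x, se = NULL)
    else stop("expected a matrix (samples x features) or MCEDExperiment")
}

.restoreType <- function(mat, holder) {
    if (is.null(holder$se)) return(mat)
    se <- holder$se
    keep <- colnames(mat)
    se <- se[keep, , drop = FALSE]
    SummarizedExperiment::assay(se, "intensity") <- t(mat)
    se
}

#' Filter features by prevalence
#'
#' Removes features observed (non-missing) in fewer than `minPrevalence` of
#' samples — the noise/dimensionality reduction step applied before
#' normalization. A report of removed features is attached as attribute
#' `"removed"`.
#'
#' @param x samples x features matrix (NA = missing) or
#'   [MCEDExperiment-class].
#' @param minPrevalence fraction in `[0,1]`; default 0.1. Features with
#'   prevalence `>= minPrevalence` are kept, so 0 is the identity.
#' @return Filtered object of the same type as `x`.
#' @export
filterFeatures <- function(x, minPrevalence = 0.1) {
    if (minPrevalence < 0 || minPrevalence > 1)
        stop("minPrevalence must lie in [0, 1]")
    h <- .asSampleMat(x)
    prev <- colMeans(!is.na(h$mat))
    keep <- prev >= minPrevalence
    if (!any(keep))
        stop(sprintf(
            "prevalence filter at %.3g removed all %d features (max prevalence %.3g)",
            minPrevalence, length(keep), max(prev)))
    out <- .restoreType(h$mat[, keep, drop = FALSE], h)
    attr(out, "removed") <- colnames(h$mat)[!keep]
    out
}

#' Fit a quantile-normalization reference on training samples
#'
#' The reference is the mean, across training samples, of each
#' sorted-intensity position. Samples with missing cells contribute through
#' linear interpolation of their sorted observed values onto the common
#' quantile grid, so missing cells are excluded from the rank pooling.
#'
#' @param train training samples x features matrix or
#'   [MCEDExperiment-class].
#' @return A [QuantileReference-class].
#' @export
quantileFit <- function(train) {
    h <- .asSampleMat(train)
    m <- h$mat
    p <- ncol(m)
    if (p < 1 || nrow(m) < 1) stop("empty training matrix")
    if (nrow(m) == 1) warning("single-sample training set: reference equals that sample's sorted values")
    grid <- if (p == 1) 0.5 else seq(0, 1, length.out = p)
    pooled <- vapply(seq_len(nrow(m)), function(i) {
        v <- sort(m[i, !is.na(m[i, ])])
        if (length(v) == 0) stop("sample with no observed features: row ", i)
        if (length(v) == 1) return(rep(v, p))
        approx(seq(0, 1, length.out = length(v)), v, xout = grid,
               rule = 2)$y
    }, numeric(p))
    ref <- rowMeans(pooled)
    methods::new("QuantileReference", referenceQuantiles = as.numeric(ref),
                 nFeatures = p)
}

## map one observed vector onto the reference distribution; ties receive the
## mean of the reference values their positions span
.quantileApplyVec <- function(v, ref) {
    obs <- which(!is.na(v))
    if (length(obs) == 0) stop("all-missing sample vector")
    p <- ref@nFeatures
    vals <- v[obs]
    m <- length(vals)
    ## reference restricted to this sample's m rank positions
    pos <- if (m == 1) (p + 1) / 2 else seq(1, p, length.out = m)
    refm <- approx(seq_len(p), ref@referenceQuantiles, xout = pos,
                   rule = 2)$y
    out <- numeric(m)
    out[order(vals)] <- refm
    out <- ave(out, match(vals, vals), FUN = mean)  # tie groups averaged
    res <- v
    res[obs] <- out
    res
}

#' Apply quantile normalization to new samples, one at a time
#'
#' Each observed value is replaced by the training reference quantile at its
#' within-sample rank (ties averaged; samples with missing cells use rank
#' interpolation over the observed positions). Applying to a training sample
#' with no ties or missing cells reproduces classic pooled quantile
#' normalization exactly, and the operation is idempotent.
#'
#' @param x numeric vector (one sample), samples x features matrix, or
#'   [MCEDExperiment-class].
#' @param reference A [QuantileReference-class] from [quantileFit()].
#' @return Normalized object of the same type as `x`; missing cells remain
#'   missing.
#' @export
quantileApply <- function(x, reference) {
    stopifnot(is(reference, "QuantileReference"))
    if (is.numeric(x) && is.null(dim(x)))
        return(.quantileApplyVec(x, reference))
    h <- .asSampleMat(x)
    if (ncol(h$mat) != reference@nFeatures)
        stop("feature count does not match the quantile reference")
    out <- t(apply(h$mat, 1, .quantileApplyVec, ref = reference))
    dimnames(out) <- dimnames(h$mat)
    .restoreType(out, h)
}

#' Log10-transform intensities
#'
#' Observed cells become `log10(value + pseudocount)`; missing cells remain
#' missing. The default pseudocount is half the smallest nonzero intensity
#' in `x` (0 if all values are strictly positive use-cases prefer an
#' explicit 0).
#'
#' @param x samples x features matrix or [MCEDExperiment-class].
#' @param pseudocount nonnegative offset; `NULL` = half the minimum nonzero
#'   value of `x`.
#' @return Transformed object of the same type as `x`, with the pseudocount
#'   used attached as attribute `"pseudocount"`.
#' @export
log10Transform <- function(x, pseudocount = NULL) {
    h <- .asSampleMat(x)
    m <- h$mat
    if (any(m < 0, na.rm = TRUE)) stop("negative intensities are not allowed")
    if (is.null(pseudocount)) {
        nz <- m[!is.na(m) & m > 0]
        pseudocount <- if (length(nz)) min(nz) / 2 else 1
    }
    if (pseudocount < 0) stop("pseudocount must be >= 0")
    if (pseudocount == 0 && any(m == 0, na.rm = TRUE))
        stop("zero intensities require a positive pseudocount")
    out <- log10(m + pseudocount)
    res <- .restoreType(out, h)
    attr(res, "pseudocount") <- pseudocount
    res
}

#' Fit / apply standard-scaler standardization
#'
#' `scaleFit()` records per-feature training means and standard deviations
#' (missing-aware); `scaleApply()` maps values to
#' `(value - train mean) / train sd`. Zero-variance features are flagged and
#' pass through centered (sd treated as 1).
#'
#' @param train,x samples x features matrix or [MCEDExperiment-class].
#' @param state A [ScalerState-class] from `scaleFit()`.
#' @return `scaleFit()`: a [ScalerState-class]; `scaleApply()`: the scaled
#'   object of the same type as `x`.
#' @export
scaleFit <- function(train) {
    h <- .asSampleMat(train)
    m <- h$mat
    if (is.null(colnames(m))) stop("training matrix must have feature names")
    mu <- colMeans(m, na.rm = TRUE)
    sdv <- apply(m, 2, sd, na.rm = TRUE)
    sdv[is.na(sdv)] <- 0       # single observation -> no spread estimate
    zero <- names(mu)[sdv == 0]
    methods::new("ScalerState", means = mu, sds = sdv, zeroVariance = zero)
}

#' @rdname scaleFit
#' @export
scaleApply <- function(x, state) {
    stopifnot(is(state, "ScalerState"))
    h <- .asSampleMat(x)
    m <- h$mat
    if (!identical(colnames(m), names(state@means))) {
        if (!all(colnames(m) %in% names(state@means)))
            stop("feature(s) absent from the scaler state")
        state <- methods::new("ScalerState",
                              means = state@means[colnames(m)],
                              sds = state@sds[colnames(m)],
                              zeroVariance = intersect(state@zeroVariance,
                                                       colnames(m)))
    }
    sdv <- state@sds
    sdv[sdv == 0] <- 1
    out <- sweep(sweep(m, 2, state@means, "-"), 2, sdv, "/")
    .restoreType(out, h)
}

## pairwise nan-Euclidean squared distances between rows of a and rows of b,
## scaled by p / (number of mutually observed features)
.nanDist2 <- function(a, b) {
    Oa <- !is.na(a); Ob <- !is.na(b)
    Za <- ifelse(Oa, a, 0); Zb <- ifelse(Ob, b, 0)
    cnt <- Oa %*% t(Ob)
    d2 <- (Za^2) %*% t(Ob) + Oa %*% t(Zb^2) - 2 * Za %*% t(Zb)
    d2[d2 < 0] <- 0                       # numerical guard
    d2 <- ifelse(cnt > 0, ncol(a) / cnt * d2, Inf)
    d2
}

## impute missing cells of target rows from pool rows (self-matches by row
## identity are excluded when poolIsTarget)
.imputeFrom <- function(target, pool, k, poolIsTarget = FALSE) {
    if (any(rowSums(!is.na(target)) == 0))
        stop("row with no observed features cannot be imputed")
    d2 <- .nanDist2(target, pool)
    if (poolIsTarget) diag(d2) <- Inf
    Opool <- !is.na(pool)
    warned <- FALSE
    out <- target
    for (i in seq_len(nrow(target))) {
        mis <- which(is.na(target[i, ]))
        if (!length(mis)) next
        ord <- order(d2[i, ])
        ord <- ord[is.finite(d2[i, ord])]
        for (f in mis) {
            cand <- ord[Opool[ord, f]]
            if (!length(cand)) next      # nothing observed anywhere: stays NA
            if (length(cand) < k && !warned) {
                warning("fewer than k neighbours available; using all")
                warned <- TRUE
            }
            out[i, f] <- mean(pool[utils::head(cand, k), f])
        }
    }
    out
}

#' K-nearest-neighbour imputation
#'
#' Fills missing cells from the `k` nearest rows by Euclidean distance over
#' mutually observed features (mean of the neighbours' observed values at
#' that feature). Under the `"uniform"` policy every row is imputed using
#' all rows as the neighbour pool (or `pool`, if given — e.g. training rows
#' when imputing a test partition). Under the `"selective"` policy each row
#' is imputed using only rows of its own class; this is the training-set
#' policy for the tissue-of-origin tier, whose test samples are deliberately
#' left non-imputed. Observed cells are never altered.
#'
#' @param x samples x features matrix or [MCEDExperiment-class].
#' @param k number of neighbours (default 5); if fewer are available, all
#'   are used with a warning.
#' @param policy `"uniform"` or `"selective"`.
#' @param labels class label per row; required for `"selective"` (taken from
#'   `colData` for an MCEDExperiment).
#' @param pool optional matrix of neighbour rows for the uniform policy;
#'   default `x` itself.
#' @return Imputed object of the same type as `x`.
#' @export
knnImpute <- function(x, k = 5, policy = c("uniform", "selective"),
                      labels = NULL, pool = NULL) {
    policy <- match.arg(policy)
    if (k < 1) stop("k must be >= 1")
    h <- .asSampleMat(x)
    m <- h$mat
    if (!anyNA(m) && is.null(pool)) return(x)
    if (policy == "uniform") {
        if (is.null(pool)) {
            out <- .imputeFrom(m, m, k, poolIsTarget = TRUE)
        } else {
            ph <- .asSampleMat(pool)
            out <- .imputeFrom(m, ph$mat, k, poolIsTarget = FALSE)
        }
    } else {
        if (is.null(labels) && !is.null(h$se)) labels <- classLabels(h$se)
        if (is.null(labels) || length(labels) != nrow(m))
            stop("selective policy requires one class label per row")
        out <- m
        for (cl in unique(labels)) {
            idx <- which(labels == cl)
            sub <- m[idx, , drop = FALSE]
            if (anyNA(sub))
                out[idx, ] <- .imputeFrom(sub, sub, k, poolIsTarget = TRUE)
        }
    }
    .restoreType(out, h)
}
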