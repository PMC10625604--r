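## The two preprocessing recipes. The detection tier (CDAI) uses
## prevalence filter -> quantile normalization -> uniform KNN imputation;
## the tissue-of-origin tier (TOOAI) uses log10 -> quantile normalization ->
## standard scaling -> selective per-class imputation of the training set,
## with test samples left non-imputed (their missing cells enter the linear
## scores as 0, i.e. at the training mean after standardization).

#' Fit / apply the CDAI preprocessing recipe
#'
#' `cdaiPrepFit()` fits on training samples only: prevalence filter,
#' quantile reference, then uniform KNN imputation of the training matrix.
#' `cdaiPrepApply()` maps new samples through the frozen state (one sample
#' at a time is fine): feature subset, quantile normalization against the
#' training reference, then KNN imputation using training rows as the
#' neighbour pool.
#'
#' @param train,x samples x features matrix (NA = missing) or
#'   [MCEDExperiment-class].
#' @param minPrevalence prevalence filter threshold (default 0.1).
#' @param k imputation neighbours (default 5).
#' @param state a fitted state from `cdaiPrepFit()`.
#' @return `cdaiPrepFit()`: list of class `"cdaiPrep"` with elements
#'   `features`, `qref`, `poolRaw` (normalized un-imputed training rows),
#'   `train` (imputed training matrix), `k`; `cdaiPrepApply()`: the
#'   processed samples x features matrix.
#' @export
cdaiPrepFit <- function(train, minPrevalence = 0.1, k = 5) {
    h <- .asSampleMat(train)
    filt <- filterFeatures(h$mat, minPrevalence)
    qref <- quantileFit(filt)
    norm <- quantileApply(filt, qref)
    imp <- knnImpute(norm, k = k, policy = "uniform")
    structure(list(features = colnames(filt), qref = qref, poolRaw = norm,
                   train = imp, k = k),
              class = "cdaiPrep")
}

#' @rdname cdaiPrepFit
#' @export
cdaiPrepApply <- function(state, x) {
    stopifnot(inherits(state, "cdaiPrep"))
    h <- .asSampleMat(x)
    m <- h$mat
    if (!all(state$features %in% colnames(m)))
        stop("sample matrix lacks features required by the preprocessing state")
    m <- m[, state$features, drop = FALSE]
    norm <- quantileApply(m, state$qref)
    knnImpute(norm, k = state$k, policy = "uniform", pool = state$poolRaw)
}

#' Fit / apply the TOOAI preprocessing recipe
#'
#' `tooaiPrepFit()` fits on training samples only: log10 transform
#' (pseudocount = half the smallest nonzero training intensity), quantile
#' reference, standard scaler, then *selective* KNN imputation within each
#' class. `tooaiPrepApply()` maps test samples through the frozen state
#' without imputing them; their remaining missing cells are scored as 0 by
#' the model (the training mean after standardization).
#'
#' @param train,x samples x features matrix or [MCEDExperiment-class].
#' @param labels class label per training row (taken from `colData` for an
#'   MCEDExperiment).
#' @param minPrevalence prevalence filter threshold (default 0.1).
#' @param k imputation neighbours (default 5).
#' @param state a fitted state from `tooaiPrepFit()`.
#' @return `tooaiPrepFit()`: list of class `"tooaiPrep"` with the frozen
#'   states and the imputed training matrix (`$train`);
#'   `tooaiPrepApply()`: the processed (non-imputed) matrix.
#' @export
tooaiPrepFit <- function(train, labels = NULL, minPrevalence = 0.1, k = 5) {
    h <- .asSampleMat(train)
    if (is.null(labels) && !is.null(h$se)) labels <- classLabels(h$se)
    if (is.null(labels) || length(labels) != nrow(h$mat))
        stop("one class label per training sample is required")
    filt <- filterFeatures(h$mat, minPrevalence)
    lg <- log10Transform(filt)
    pc <- attr(lg, "pseudocount")
    qref <- quantileFit(lg)
    norm <- quantileApply(lg, qref)
    scaler <- scaleFit(norm)
    scaled <- scaleApply(norm, scaler)
    imp <- knnImpute(scaled, k = k, policy = "selective", labels = labels)
    structure(list(features = colnames(filt), pseudocount = pc, qref = qref,
                   scaler = scaler, train = imp, k = k),
              class = "tooaiPrep")
}

#' @rdname tooaiPrepFit
#' @export
tooaiPrepApply <- function(state, x) {
    stopifnot(inherits(state, "tooaiPrep"))
    h <- .asSampleMat(x)
    m <- h$mat
    if (!all(state$features %in% colnames(m)))
        stop("sample matrix lacks features required by the preprocessing state")
    m <- m[, state$features, drop = FALSE]
    lg <- log10Transform(m, pseudocount = state$pseudocount)
    norm <- quantileApply(lg, state$qref)
    scaleApply(norm, state$scaler)
}
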