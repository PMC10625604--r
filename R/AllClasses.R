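#' MCEDExperiment: aligned feature matrix with sample metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay,
#' `"intensity"` (features in rows, samples in columns, `NA` marking
#' missing/unobserved cells), with `colData` columns `class_label` and
#' `batch_id`. Row metadata carries the VLM box and metabolite annotation
#' when built by [assembleMatrix()].
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment]; no extra slots.
#' @export
setClass("MCEDExperiment", contains = "SummarizedExperiment")

setValidity("MCEDExperiment", function(object) {
    msg <- NULL
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'intensity' is required")
    cd <- SummarizedExperiment::colData(object)
    for (col in c("class_label", "batch_id"))
        if (!col %in% colnames(cd))
            msg <- c(msg, sprintf("colData column '%s' is required", col))
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be unique")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "feature ids (rownames) must be unique")
    if (is.null(msg)) TRUE else msg
})

#' VLMBoxSet: virtual lock-mass windows
#'
#' One ppm-tolerance mass window per reference metabolite. Windows are
#' `center_mass * (1 +/- tol_ppm * 1e-6)` and are stored sorted by center
#' mass; `overlaps` reports pairs of windows that intersect (reference
#' masses closer than ~2*tol ppm).
#'
#' @slot boxes data.frame with columns `box_id`, `metabolite_id`,
#'   `center_mass`, `mass_low`, `mass_high`, sorted by `center_mass`.
#' @slot tolPpm numeric(1), the half-width tolerance in ppm.
#' @slot overlaps data.frame with columns `box_id_1`, `box_id_2` listing
#'   overlapping window pairs (may have zero rows).
#' @export
setClass("VLMBoxSet", representation(
    boxes = "data.frame", tolPpm = "numeric", overlaps = "data.frame"))

setValidity("VLMBoxSet", function(object) {
    b <- object@boxes
    msg <- NULL
    need <- c("box_id", "metabolite_id", "center_mass", "mass_low", "mass_high")
    if (!all(need %in% colnames(b)))
        msg <- c(msg, "boxes must have box_id, metabolite_id, center_mass, mass_low, mass_high")
    else {
        if (is.unsorted(b$center_mass)) msg <- c(msg, "boxes must be sorted by center_mass")
        if (anyDuplicated(b$box_id)) msg <- c(msg, "box_id must be unique")
        if (any(b$mass_low > b$center_mass | b$mass_high < b$center_mass))
            msg <- c(msg, "each window must contain its center mass")
    }
    if (length(object@tolPpm) != 1L || object@tolPpm <= 0)
        msg <- c(msg, "tolPpm must be a single positive number")
    if (is.null(msg)) TRUE else msg
})

#' QuantileReference: training quantile distribution
#'
#' Mean sorted-intensity vector pooled over training samples; the target
#' distribution that [quantileApply()] maps new samples onto, one sample at
#' a time.
#'
#' @slot referenceQuantiles numeric, nondecreasing, one value per feature
#'   rank position.
#' @slot nFeatures integer(1), number of features the reference was fit on.
#' @export
setClass("QuantileReference", representation(
    referenceQuantiles = "numeric", nFeatures = "integer"))

setValidity("QuantileReference", function(object) {
    msg <- NULL
    if (length(object@referenceQuantiles) != object@nFeatures)
        msg <- c(msg, "referenceQuantiles length must equal nFeatures")
    if (is.unsorted(object@referenceQuantiles, na.rm = TRUE))
        msg <- c(msg, "referenceQuantiles must be nondecreasing")
    if (is.null(msg)) TRUE else msg
})

#' ScalerState: per-feature standardization parameters
#'
#' Training means and standard deviations for standard-scaler
#' standardization. Zero-variance features are flagged and scaled with a
#' standard deviation of 1 (so they center to zero).
#'
#' @slot means named numeric, per-feature training mean.
#' @slot sds named numeric, per-feature training standard deviation.
#' @slot zeroVariance character, ids of flagged zero-variance features.
#' @export
setClass("ScalerState", representation(
    means = "numeric", sds = "numeric", zeroVariance = "character"))

setValidity("ScalerState", function(object) {
    msg <- NULL
    if (length(object@means) != length(object@sds))
        msg <- c(msg, "means and sds must have equal length")
    if (!identical(names(object@means), names(object@sds)))
        msg <- c(msg, "means and sds must share feature names")
    if (any(object@sds < 0, na.rm = TRUE))
        msg <- c(msg, "standard deviations must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' CDAIModel: tier-1 binary cancer-detection scorer
#'
#' Linear score `y_score = x0 + sum_i x_i * I_i` over the selected feature
#' intensities, with a threshold (default 0) separating cancer (score at or
#' above threshold) from normal.
#'
#' @slot intercept numeric(1), the constant term x0.
#' @slot coefficients named numeric, x_1..x_n aligned to `featureIds`.
#' @slot featureIds character, ordered feature ids.
#' @slot threshold numeric(1), decision threshold on the score.
#' @export
setClass("CDAIModel", representation(
    intercept = "numeric", coefficients = "numeric",
    featureIds = "character", threshold = "numeric"))

setValidity("CDAIModel", function(object) {
    msg <- NULL
    if (length(object@coefficients) != length(object@featureIds))
        msg <- c(msg, "coefficient vector length must equal feature count")
    if (!is.finite(object@threshold)) msg <- c(msg, "threshold must be finite")
    if (!is.finite(object@intercept)) msg <- c(msg, "intercept must be finite")
    if (is.null(msg)) TRUE else msg
})

#' TOOAIModel: tier-2 tissue-of-origin multiclass scorer
#'
#' One-vs-rest linear scorers, one per cancer class; each class k emits
#' `P(k) = 1 / (1 + exp(-(a_k + w_k . I)))`, i.e. a sigmoid-mapped linear
#' score, and decisions use the top-1 and top-2 scored classes.
#'
#' @slot classLabels character, ordered class labels (15 cancers at study
#'   scale; any K >= 2 in general).
#' @slot intercepts named numeric, one per class.
#' @slot weights numeric matrix, classes x features.
#' @slot featureIds character, feature order of the weight columns.
#' @slot family character(1), `"max-margin"` or `"logistic-ovr"`.
#' @export
setClass("TOOAIModel", representation(
    classLabels = "character", intercepts = "numeric", weights = "matrix",
    featureIds = "character", family = "character"))

setValidity("TOOAIModel", function(object) {
    msg <- NULL
    K <- length(object@classLabels)
    if (length(object@intercepts) != K)
        msg <- c(msg, "one intercept per class required")
    if (nrow(object@weights) != K)
        msg <- c(msg, "one weight vector per class required")
    if (ncol(object@weights) != length(object@featureIds))
        msg <- c(msg, "weight columns must align to featureIds")
    if (!all(is.finite(object@intercepts)) || !all(is.finite(object@weights)))
        msg <- c(msg, "all intercepts and weights must be finite")
    if (is.null(msg)) TRUE else msg
})
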