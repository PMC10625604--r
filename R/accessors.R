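#' Construct an MCEDExperiment
#'
#' @param intensities numeric matrix, features x samples, `NA` = missing.
#' @param classLabels character, one label per sample.
#' @param batchIds vector, one batch id per sample.
#' @param rowData optional data.frame of per-feature annotation.
#' @return An [MCEDExperiment-class].
#' @export
MCEDExperiment <- function(intensities, classLabels, batchIds, rowData = NULL) {
    if (is.null(colnames(intensities)))
        stop("intensities must have sample ids as colnames")
    if (is.null(rownames(intensities)))
        stop("intensities must have feature ids as rownames")
    if (length(classLabels) != ncol(intensities) ||
        length(batchIds) != ncol(intensities))
        stop("classLabels and batchIds must have one entry per sample")
    cd <- S4Vectors::DataFrame(
        class_label = as.character(classLabels),
        batch_id = batchIds, row.names = colnames(intensities))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = intensities), colData = cd)
    if (!is.null(rowData))
        SummarizedExperiment::rowData(se) <- S4Vectors::DataFrame(rowData)
    methods::new("MCEDExperiment", se)
}

#' Accessors for MCEDExperiment
#'
#' `intensityMatrix()` returns the features x samples assay; `sampleMatrix()`
#' its transpose (samples in rows, the orientation the statistical functions
#' use); `classLabels()` and `batchIds()` the per-sample metadata;
#' `missingMask()` a logical matrix marking missing cells (same shape as
#' `intensityMatrix()`).
#'
#' @param x An [MCEDExperiment-class].
#' @return See description.
#' @name mced-accessors
#' @aliases intensityMatrix sampleMatrix classLabels batchIds missingMask
NULL

#' @rdname mced-accessors
#' @export
intensityMatrix <- function(x) SummarizedExperiment::assay(x, "intensity")

#' @rdname mced-accessors
#' @export
sampleMatrix <- function(x) t(SummarizedExperiment::assay(x, "intensity"))

#' @rdname mced-accessors
#' @export
classLabels <- function(x) SummarizedExperiment::colData(x)$class_label

#' @rdname mced-accessors
#' @export
batchIds <- function(x) SummarizedExperiment::colData(x)$batch_id

#' @rdname mced-accessors
#' @export
missingMask <- function(x) is.na(SummarizedExperiment::assay(x, "intensity"))

#' @describeIn MCEDExperiment compact display with missingness and label
#'   summary.
#' @param object An `MCEDExperiment`.
#' @export
setMethod("show", "MCEDExperiment", function(object) {
    cat(sprintf("MCEDExperiment: %d features x %d samples\n",
                nrow(object), ncol(object)))
    m <- mean(is.na(SummarizedExperiment::assay(object, "intensity")))
    cat(sprintf("  missing cells: %.1f%%\n", 100 * m))
    tab <- table(classLabels(object))
    cat(sprintf("  classes (%d): %s\n", length(tab),
                paste(utils::head(names(tab), 6), collapse = ", ")))
    cat(sprintf("  batches: %d\n", length(unique(batchIds(object)))))
})

#' Accessors for VLMBoxSet
#'
#' `boxTable()` returns the window table, `boxOverlaps()` the overlapping
#' window pairs, `tolPpm()` the ppm tolerance.
#' @param x A [VLMBoxSet-class].
#' @name vlm-accessors
NULL

#' @rdname vlm-accessors
#' @export
boxTable <- function(x) x@boxes

#' @rdname vlm-accessors
#' @export
boxOverlaps <- function(x) x@overlaps

#' @rdname vlm-accessors
#' @export
tolPpm <- function(x) x@tolPpm

#' @describeIn VLMBoxSet display box count, tolerance and overlap count.
#' @param object A `VLMBoxSet`.
#' @export
setMethod("show", "VLMBoxSet", function(object) {
    cat(sprintf("VLMBoxSet: %d boxes, tolerance %.3g ppm, %d overlapping pairs\n",
                nrow(object@boxes), object@tolPpm, nrow(object@overlaps)))
    cat(sprintf("  mass range: %.4f - %.4f Da\n",
                min(object@boxes$mass_low), max(object@boxes$mass_high)))
})

#' Coefficients of a CDAI model
#'
#' @param object A [CDAIModel-class].
#' @param ... unused.
#' @return Named numeric vector `c(intercept, x_1..x_n)`.
#' @export
setMethod("coef", "CDAIModel", function(object, ...) {
    c("(Intercept)" = object@intercept, object@coefficients)
})

#' @describeIn CDAIModel display feature count and threshold.
#' @param object A `CDAIModel`.
#' @export
setMethod("show", "CDAIModel", function(object) {
    cat(sprintf("CDAIModel: linear score over %d features, threshold %.3g\n",
                length(object@featureIds), object@threshold))
    cat(sprintf("  intercept x0 = %.6g\n", object@intercept))
})

#' @describeIn TOOAIModel display class and feature counts.
#' @param object A `TOOAIModel`.
#' @export
setMethod("show", "TOOAIModel", function(object) {
    cat(sprintf("TOOAIModel (%s): %d one-vs-rest scorers over %d features\n",
                object@family, length(object@classLabels),
                length(object@featureIds)))
    cat(sprintf("  classes: %s%s\n",
                paste(utils::head(object@classLabels, 5), collapse = ", "),
                if (length(object@classLabels) > 5) ", ..." else ""))
})

#' @describeIn QuantileReference display length and range.
#' @param object A `QuantileReference`.
#' @export
setMethod("show", "QuantileReference", function(object) {
    cat(sprintf("QuantileReference: %d quantile positions, range [%.4g, %.4g]\n",
                object@nFeatures, min(object@referenceQuantiles),
                max(object@referenceQuantiles)))
})

#' @describeIn ScalerState display feature count and flags.
#' @param object A `ScalerState`.
#' @export
setMethod("show", "ScalerState", function(object) {
    cat(sprintf("ScalerState: %d features, %d flagged zero-variance\n",
                length(object@means), length(object@zeroVariance)))
})
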