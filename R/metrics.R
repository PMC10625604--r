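## Confusion-count metrics and rank-based ROC-AUC.

#' Confusion counts for binary calls
#'
#' @param predicted,actual character vectors of `"cancer"` / `"normal"`
#'   calls (or any two labels with `positive` naming the positive one).
#' @param positive the positive-class label (default `"cancer"`).
#' @return Named integer vector with `TP`, `TN`, `FP`, `FN`.
#' @export
confusionCounts <- function(predicted, actual, positive = "cancer") {
    if (length(predicted) != length(actual))
        stop("predicted and actual must have equal length")
    p <- predicted == positive
    a <- actual == positive
    c(TP = sum(p & a), TN = sum(!p & !a), FP = sum(p & !a), FN = sum(!p & a))
}

.counts <- function(counts) {
    need <- c("TP", "TN", "FP", "FN")
    if (!all(need %in% names(counts))) stop("counts must carry TP, TN, FP, FN")
    if (any(counts[need] < 0)) stop("counts must be nonnegative")
    counts[need]
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `accuracy = (TP+TN)/total`, each as a percentage. A zero denominator is
#' an error (the metric is undefined). [formatPct()] renders a percentage at
#' the conventional one-decimal precision (round-half-even).
#'
#' @param counts named vector with `TP`, `TN`, `FP`, `FN` (from
#'   [confusionCounts()]).
#' @return Numeric percentage in `[0, 100]`.
#' @examples
#' sensitivity(c(TP = 124, FN = 1, TN = 0, FP = 0))  # 99.2
#' @export
sensitivity <- function(counts) {
    cc <- .counts(counts)
    den <- cc["TP"] + cc["FN"]
    if (den == 0) stop("sensitivity undefined: TP + FN == 0")
    as.numeric(100 * cc["TP"] / den)
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
    cc <- .counts(counts)
    den <- cc["TN"] + cc["FP"]
    if (den == 0) stop("specificity undefined: TN + FP == 0")
    as.numeric(100 * cc["TN"] / den)
}

#' @rdname sensitivity
#' @export
accuracy <- function(counts) {
    cc <- .counts(counts)
    den <- sum(cc)
    if (den == 0) stop("accuracy undefined: no counts")
    as.numeric(100 * (cc["TP"] + cc["TN"]) / den)
}

#' @rdname sensitivity
#' @param pct percentage to format.
#' @export
formatPct <- function(pct) sprintf("%.1f", round(pct, 1))

#' Rank-based ROC-AUC
#'
#' Concordance probability computed from midranks (tie-corrected), equal to
#' the Mann-Whitney U statistic divided by `n_pos * n_neg`; invariant under
#' strictly monotone transforms of the scores.
#'
#' @param scores numeric scores (larger = more positive).
#' @param labels class label per score.
#' @param positive the positive-class label (default `"cancer"`).
#' @return AUC in `[0, 1]`.
#' @export
rocAuc <- function(scores, labels, positive = "cancer") {
    pos <- labels == positive
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) stop("both classes must be present")
    r <- rank(scores)            # midranks handle ties
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
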