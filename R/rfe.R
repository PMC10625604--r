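## Recursive feature elimination: iteratively refit a linear model and drop
## the feature with the smallest absolute weight, one at a time, until a
## total ranking is produced (rank 1 = last survivor).

#' Default RFE trainer: ridge logistic weights
#'
#' Fits an L2-regularized logistic regression (cancer vs normal) and
#' returns the per-feature coefficients; the shape of trainer [rfeRank()]
#' expects.
#'
#' @param x samples x features matrix (complete).
#' @param labels binary labels (two distinct values; the lexicographically
#'   larger one is modelled as the positive class).
#' @param regularization ridge penalty lambda (default 1).
#' @return Named numeric vector of feature weights.
#' @export
ridgeLogisticTrainer <- function(x, labels, regularization = 1) {
    f <- factor(labels)
    if (nlevels(f) != 2) stop("trainer expects exactly two classes")
    if (ncol(x) == 1) {
        ## glmnet needs >= 2 columns; pad with a zero column
        xx <- cbind(x, .pad = 0)
        fit <- glmnet::glmnet(xx, f, family = "binomial", alpha = 0,
                              lambda = regularization, standardize = TRUE,
                              thresh = 1e-12)
        w <- as.numeric(fit$beta)[1]
        return(setNames(w, colnames(x)))
    }
    fit <- glmnet::glmnet(x, f, family = "binomial", alpha = 0,
                          lambda = regularization, standardize = TRUE,
                          thresh = 1e-12)
    setNames(as.numeric(fit$beta), rownames(fit$beta))
}

#' Rank features by recursive feature elimination
#'
#' At each step the trainer is refit on the surviving features and the
#' feature with the smallest absolute weight is eliminated (ties broken
#' toward the lexicographically first feature id); the last survivor gets
#' rank 1. With `stepSize > 1` that many features are dropped per refit,
#' trading fidelity for speed at large feature counts.
#'
#' @param x samples x features matrix (complete, with column names) or
#'   [MCEDExperiment-class].
#' @param labels class labels passed to the trainer.
#' @param trainer function `(x, labels) -> named weights`, one weight per
#'   column of `x`; default [ridgeLogisticTrainer()].
#' @param stepSize features eliminated per refit (default 1).
#' @return data.frame of class `"featureRanking"` with columns
#'   `feature_id`, `rank`, `weight_at_elimination`, ordered by rank.
#' @export
rfeRank <- function(x, labels, trainer = ridgeLogisticTrainer, stepSize = 1) {
    h <- .asSampleMat(x)
    m <- h$mat
    if (is.null(colnames(m))) stop("feature names are required")
    if (is(x, "MCEDExperiment") && missing(labels)) labels <- classLabels(x)
    remaining <- colnames(m)
    ranks <- data.frame(feature_id = character(0), rank = integer(0),
                        weight_at_elimination = numeric(0))
    while (length(remaining) > 0) {
        w <- trainer(m[, remaining, drop = FALSE], labels)
        if (!is.numeric(w) || is.null(names(w)) ||
            !setequal(names(w), remaining))
            stop("trainer must return one named weight per feature")
        w <- w[remaining]
        if (length(remaining) == 1) {
            ranks <- rbind(ranks, data.frame(
                feature_id = remaining, rank = 1L,
                weight_at_elimination = unname(w)))
            break
        }
        nDrop <- min(stepSize, length(remaining) - 1)
        ## order by |weight| then feature id: lexicographic tie-break
        ord <- order(abs(w), names(w))
        drop <- names(w)[ord[seq_len(nDrop)]]
        rk <- seq(length(remaining), by = -1L, length.out = nDrop)
        ranks <- rbind(ranks, data.frame(
            feature_id = drop, rank = as.integer(rk),
            weight_at_elimination = unname(w[drop])))
        remaining <- setdiff(remaining, drop)
    }
    ranks <- ranks[order(ranks$rank), , drop = FALSE]
    rownames(ranks) <- NULL
    class(ranks) <- c("featureRanking", "data.frame")
    ranks
}
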