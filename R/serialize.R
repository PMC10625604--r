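## Structured-text serialization of models and preprocessing states, so a
## trained pipeline can be frozen and reapplied at scoring time.

#' Serialize / restore a CDAI model as structured text
#'
#' The file holds `threshold`, `intercept`, then one `feature_id<TAB>coef`
#' line per feature.
#'
#' @param model A [CDAIModel-class].
#' @param path file path.
#' @return `writeCDAIModel()`: `path`, invisibly; `readCDAIModel()`: the
#'   [CDAIModel-class].
#' @export
writeCDAIModel <- function(model, path) {
    stopifnot(is(model, "CDAIModel"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("threshold\t%.17g", model@threshold), con)
    writeLines(sprintf("intercept\t%.17g", model@intercept), con)
    writeLines(sprintf("%s\t%.17g", model@featureIds, model@coefficients),
               con)
    invisible(path)
}

#' @rdname writeCDAIModel
#' @export
readCDAIModel <- function(path) {
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    thr <- as.numeric(tab$V2[tab$V1 == "threshold"])
    ic <- as.numeric(tab$V2[tab$V1 == "intercept"])
    rest <- tab[!(tab$V1 %in% c("threshold", "intercept")), ]
    methods::new("CDAIModel", intercept = ic,
                 coefficients = setNames(as.numeric(rest$V2), rest$V1),
                 featureIds = rest$V1, threshold = thr)
}

#' Serialize / restore a TOOAI model as structured text
#'
#' The file holds the family, one intercept line per class, then a
#' class x feature weight table.
#'
#' @param model A [TOOAIModel-class].
#' @param stem path stem; writes `<stem>.meta.tsv` and `<stem>.weights.tsv`.
#' @return `writeTOOAIModel()`: `stem`, invisibly; `readTOOAIModel()`: the
#'   [TOOAIModel-class].
#' @export
writeTOOAIModel <- function(model, stem) {
    stopifnot(is(model, "TOOAIModel"))
    writeTable(data.frame(class_label = model@classLabels,
                          family = model@family,
                          intercept = sprintf("%.17g", model@intercepts)),
               paste0(stem, ".meta.tsv"))
    w <- data.frame(class_label = model@classLabels,
                    model@weights, check.names = FALSE)
    writeTable(w, paste0(stem, ".weights.tsv"))
    invisible(stem)
}

#' @rdname writeTOOAIModel
#' @export
readTOOAIModel <- function(stem) {
    meta <- readTable(paste0(stem, ".meta.tsv"))
    w <- readTable(paste0(stem, ".weights.tsv"))
    stopifnot(identical(meta$class_label, w$class_label))
    W <- as.matrix(w[, -1, drop = FALSE])
    rownames(W) <- w$class_label
    methods::new("TOOAIModel", classLabels = meta$class_label,
                 intercepts = setNames(as.numeric(meta$intercept),
                                       meta$class_label),
                 weights = W, featureIds = colnames(W),
                 family = meta$family[1])
}

#' Serialize / restore preprocessing states as structured text
#'
#' @param state A [QuantileReference-class] or [ScalerState-class].
#' @param path file path.
#' @return Writers return `path` invisibly; readers the restored object.
#' @export
writeQuantileReference <- function(state, path) {
    stopifnot(is(state, "QuantileReference"))
    writeTable(data.frame(position = seq_len(state@nFeatures),
                          quantile = sprintf("%.17g",
                                             state@referenceQuantiles)),
               path)
}

#' @rdname writeQuantileReference
#' @export
readQuantileReference <- function(path) {
    tab <- readTable(path)
    methods::new("QuantileReference",
                 referenceQuantiles = as.numeric(tab$quantile),
                 nFeatures = nrow(tab))
}

#' @rdname writeQuantileReference
#' @export
writeScalerState <- function(state, path) {
    stopifnot(is(state, "ScalerState"))
    writeTable(data.frame(feature_id = names(state@means),
                          mean = sprintf("%.17g", state@means),
                          sd = sprintf("%.17g", state@sds),
                          zero_variance = names(state@means) %in%
                              state@zeroVariance),
               path)
}

#' @rdname writeQuantileReference
#' @export
readScalerState <- function(path) {
    tab <- readTable(path)
    methods::new("ScalerState",
                 means = setNames(as.numeric(tab$mean), tab$feature_id),
                 sds = setNames(as.numeric(tab$sd), tab$feature_id),
                 zeroVariance = tab$feature_id[tab$zero_variance])
}
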