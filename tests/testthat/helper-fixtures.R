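## Shared fixtures, all generated in code.

## small cohort with a clear class signal; returns generator inputs plus the
## aligned & trimmed experiment
makeToyCohort <- function(nMet = 80, classes = c("normal", "lungX", "gutX"),
                          perClass = 10, nAffected = 10, effectSize = 0.8,
                          ppmErrorSd = 5 / 3, dropoutRate = 0.05,
                          noiseSd = 0.2, seed = 42) {
    ref <- generateReference(nMet, seed = seed)
    prof <- makeClassProfiles(ref, classes, nAffected = nAffected,
                              effectSize = effectSize, seed = seed + 1)
    cfg <- cohortConfig(setNames(rep(perClass, length(classes)), classes),
                        ppmErrorSd = ppmErrorSd, dropoutRate = dropoutRate,
                        intensityNoiseSd = noiseSd, seed = seed + 2)
    cohort <- generateCohort(ref, prof, cfg)
    boxes <- buildBoxes(ref, 5)
    se <- trimMatrix(alignCohort(cohort$peaks, cohort$truth, boxes), ref)
    list(reference = ref, profiles = prof, config = cfg,
         peaks = cohort$peaks, truth = cohort$truth, boxes = boxes, se = se)
}

## complete (no-missing) labelled matrix with informative first feature
makeSeparableMatrix <- function(n = 30, p = 8, gap = 4, seed = 7) {
    set.seed(seed)
    y <- rep(c("cancer", "normal"), length.out = n)
    m <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("S%02d", 1:n),
                                sprintf("F%02d", 1:p)))
    m[, 1] <- m[, 1] + ifelse(y == "cancer", gap, 0)
    list(x = m, y = y)
}

## brute-force nearest-ppm oracle for peak-to-box assignment, with the
## lower-mass tie-break
oracleAssign <- function(mz, boxes) {
    b <- boxTable(boxes)
    vapply(mz, function(z) {
        dev <- abs(z - b$center_mass) / b$center_mass * 1e6
        inside <- z >= b$mass_low & z <= b$mass_high
        if (!any(inside)) return(NA_character_)
        cand <- which(inside)
        best <- cand[dev[cand] == min(dev[cand])]
        b$box_id[best[which.min(b$center_mass[best])]]
    }, character(1))
}

## brute-force pooled quantile normalization for complete matrices
oracleQuantileFit <- function(m) rowMeans(apply(m, 1, sort))

oracleQuantileApply <- function(v, ref) {
    out <- numeric(length(v))
    out[order(v)] <- ref
    ## ties: average the reference values the tied group spans
    ave(out, match(v, v), FUN = mean)
}

## exhaustive KNN imputation oracle (complete-pool case)
oracleKnnImpute <- function(m, k) {
    out <- m
    p <- ncol(m)
    for (i in seq_len(nrow(m))) {
        mis <- which(is.na(m[i, ]))
        for (f in mis) {
            d <- rep(Inf, nrow(m))
            for (j in seq_len(nrow(m))) {
                if (j == i) next
                mut <- !is.na(m[i, ]) & !is.na(m[j, ])
                if (!any(mut)) next
                d[j] <- sqrt(p / sum(mut) * sum((m[i, mut] - m[j, mut])^2))
            }
            cand <- order(d)
            cand <- cand[is.finite(d[cand]) & !is.na(m[cand, f])]
            if (length(cand))
                out[i, f] <- mean(m[head(cand, k), f])
        }
    }
    out
}

## exhaustive pairwise-comparison AUC oracle
oracleAuc <- function(scores, labels, positive = "cancer") {
    pos <- which(labels == positive)
    neg <- which(labels != positive)
    tot <- 0
    for (i in pos) for (j in neg)
        tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    tot / (length(pos) * length(neg))
}
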