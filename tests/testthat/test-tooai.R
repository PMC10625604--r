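makeMulticlassToy <- function(n = 60, K = 3, gap = 4, seed = 1) {
    set.seed(seed)
    y <- rep(paste0("class", seq_len(K)), length.out = n)
    x <- matrix(rnorm(n * (K + 2)), n, K + 2,
                dimnames = list(paste0("s", 1:n),
                                sprintf("f%02d", seq_len(K + 2))))
    for (k in seq_len(K))
        x[y == paste0("class", k), k] <- x[y == paste0("class", k), k] + gap
    list(x = x, y = y)
}

test_that("a separable multiclass toy trains to perfect top-1 accuracy", {
    toy <- makeMulticlassToy(gap = 5, seed = 2)
    model <- trainTOOAI(toy$x, toy$y, grid = 1)
    pred <- tooaiPredict(model, toy$x)
    expect_equal(mean(pred$top1 == toy$y), 1)
    ## refits are identical
    model2 <- trainTOOAI(toy$x, toy$y, grid = 1)
    expect_identical(model@weights, model2@weights)
    expect_identical(model@intercepts, model2@intercepts)
})

test_that("missing training classes are reported by name", {
    toy <- makeMulticlassToy(seed = 3)
    expect_error(trainTOOAI(toy$x, toy$y,
                            classLabels = c(unique(toy$y), "liverX", "gastricX")),
                 "liverX, gastricX")
})

test_that("predicted scores are sigmoids of the per-class linear score", {
    set.seed(4)
    K <- 4; p <- 6
    W <- matrix(rnorm(K * p), K, p,
                dimnames = list(paste0("c", 1:K), paste0("f", 1:p)))
    b <- setNames(rnorm(K), paste0("c", 1:K))
    model <- methods::new("TOOAIModel", classLabels = paste0("c", 1:K),
                          intercepts = b, weights = W,
                          featureIds = paste0("f", 1:p), family = "max-margin")
    v <- setNames(rnorm(p), paste0("f", 1:p))
    pred <- tooaiPredict(model, v)
    want <- 1 / (1 + exp(-(b + as.numeric(W %*% v))))
    expect_equal(unname(pred$scores[1, ]), unname(want), tolerance = 1e-12)
    expect_true(all(pred$scores > 0 & pred$scores < 1))
    ## top1/top2 are the two largest scores in descending order
    ord <- names(sort(want, decreasing = TRUE))
    expect_equal(unname(pred$top2[1, ]), ord[1:2])
})

test_that("all-zero weights score 0.5 everywhere with lexicographic top-2", {
    model <- methods::new("TOOAIModel",
                          classLabels = c("breastX", "cervicalX", "ovarianX"),
                          intercepts = setNames(numeric(3),
                                                c("breastX", "cervicalX",
                                                  "ovarianX")),
                          weights = matrix(0, 3, 2,
                                           dimnames = list(NULL, c("f1", "f2"))),
                          featureIds = c("f1", "f2"), family = "max-margin")
    pred <- tooaiPredict(model, c(f1 = 1, f2 = -1))
    expect_equal(unname(pred$scores[1, ]), rep(0.5, 3))
    expect_equal(unname(pred$top2[1, ]), c("breastX", "cervicalX"))
})

test_that("a dominant class margin drives its score toward 1 and top-1", {
    model <- methods::new("TOOAIModel", classLabels = c("a", "b"),
                          intercepts = c(a = 10, b = -10),
                          weights = matrix(0, 2, 1,
                                           dimnames = list(NULL, "f1")),
                          featureIds = "f1", family = "max-margin")
    pred <- tooaiPredict(model, c(f1 = 0))
    expect_gt(pred$scores[1, "a"], 0.99)
    expect_equal(pred$top1, "a")
})

test_that("double-class accuracy matches hand enumeration and bounds top-1", {
    labels <- c("A", "B", "C")
    scores <- rbind(c(0.9, 0.5, 0.1),   # truth A: top1 hit
                    c(0.6, 0.8, 0.1),   # truth A: rescued by top2
                    c(0.1, 0.2, 0.9),   # truth A: miss
                    c(0.3, 0.9, 0.5),   # truth B: top1 hit
                    c(0.9, 0.2, 0.5),   # truth C: miss (top2 = A, C? -> A,C)
                    c(0.2, 0.3, 0.8))   # truth C: top1 hit
    colnames(scores) <- labels
    tops <- t(apply(scores, 1, function(v)
        labels[order(-v, labels)][1:2]))
    pred <- structure(list(scores = scores, top1 = tops[, 1], top2 = tops,
                           classLabels = labels), class = "tooaiPrediction")
    truths <- c("A", "A", "A", "B", "C", "C")
    acc <- doubleClassAccuracy(pred, truths)
    ## hand enumeration: hits = rows 1,2,4,5(top2 = A,C contains C),6 -> 5/6
    expect_equal(acc$overall, 100 * 5 / 6)
    expect_equal(acc$top1, 100 * 3 / 6)
    expect_gte(acc$overall, acc$top1)
    pc <- acc$perClass
    expect_equal(pc$correct[pc$class == "A"], 2)
    expect_equal(pc$tested[pc$class == "A"], 3)

    expect_error(doubleClassAccuracy(pred, c(truths[-1], "Z")), "unknown")
})

test_that("double-class confusion credits top-2 hits to the diagonal and conserves rows", {
    toy <- makeMulticlassToy(n = 90, K = 3, gap = 5, seed = 6)
    model <- trainTOOAI(toy$x, toy$y, grid = 1)
    pred <- tooaiPredict(model, toy$x)
    cm <- doubleClassConfusion(pred, toy$y)
    expect_equal(unname(rowSums(cm)), unname(as.vector(table(toy$y))))
    ## separable toy: everything on the diagonal
    expect_equal(sum(diag(cm)), 90)

    ## noisy random scores still conserve row sums
    set.seed(7)
    labels <- sort(unique(toy$y))
    sc <- matrix(runif(30 * 3), 30, 3, dimnames = list(NULL, labels))
    tops <- t(apply(sc, 1, function(v) labels[order(-v, labels)][1:2]))
    predR <- structure(list(scores = sc, top1 = tops[, 1], top2 = tops,
                            classLabels = labels), class = "tooaiPrediction")
    truthsR <- sample(labels, 30, TRUE)
    cmR <- doubleClassConfusion(predR, truthsR)
    expect_equal(unname(rowSums(cmR)),
                 unname(as.vector(table(factor(truthsR, levels = labels)))))
    ## off-diagonal entries sit at (truth, top1)
    accR <- doubleClassAccuracy(predR, truthsR)
    expect_equal(sum(diag(cmR)), round(accR$overall / 100 * 30))
})

test_that("top-2 accuracy approaches top-1 as separation grows", {
    accGap <- vapply(c(1, 6), function(gap) {
        toy <- makeMulticlassToy(n = 90, K = 3, gap = gap, seed = 8)
        tr <- seq_len(90) %% 2 == 0
        model <- trainTOOAI(toy$x[tr, ], toy$y[tr], grid = 1)
        pred <- tooaiPredict(model, toy$x[!tr, ])
        acc <- doubleClassAccuracy(pred, toy$y[!tr])
        acc$overall - acc$top1
    }, numeric(1))
    expect_lte(accGap[2], accGap[1])   # margin shrinks with separation
    ## and it is always nonnegative
    expect_true(all(accGap >= 0))
})

test_that("TOOAI cross-validation reports top-2 >= top-1 per split", {
    toy <- makeToyCohort(nMet = 60, classes = c("lungX", "gutX", "skinX"),
                         perClass = 12, nAffected = 12, effectSize = 1,
                         seed = 13)
    m <- sampleMatrix(toy$se)
    cv <- suppressWarnings(
        crossValidateTOOAI(m, classLabels(toy$se), nSplits = 4, seed = 2))
    expect_true(all(cv$perSplit$top2 >= cv$perSplit$top1))
    expect_equal(nrow(cv$perSplit), 4)
})
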