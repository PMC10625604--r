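test_that("training on a separable toy yields perfect training metrics", {
    sep <- makeSeparableMatrix(n = 30, p = 5, gap = 6, seed = 1)
    model <- trainCDAI(sep$x, sep$y)
    calls <- cdaiClassify(cdaiScore(model, sep$x), model@threshold)
    cc <- confusionCounts(calls, sep$y)
    expect_equal(sensitivity(cc), 100)
    expect_equal(specificity(cc), 100)
})

test_that("training is deterministic and rejects single-class input", {
    sep <- makeSeparableMatrix(n = 20, p = 4, seed = 2)
    m1 <- trainCDAI(sep$x, sep$y)
    m2 <- trainCDAI(sep$x, sep$y)
    expect_identical(coef(m1), coef(m2))
    expect_error(trainCDAI(sep$x, rep("cancer", 20)), "normal")
})

test_that("class balancing does not hurt minority-class recall under 9:1 imbalance", {
    set.seed(3)
    n <- 200
    y <- c(rep("cancer", 180), rep("normal", 20))
    x <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(paste0("s", 1:n), paste0("f", 1:4)))
    ## overlapping classes: modest shift
    x[, 1] <- x[, 1] + ifelse(y == "cancer", 0.8, 0)
    mBal <- trainCDAI(x, y, balance = TRUE)
    mUnb <- trainCDAI(x, y, balance = FALSE)
    recall <- function(model) {
        calls <- cdaiClassify(cdaiScore(model, x), model@threshold)
        cc <- confusionCounts(calls, y)
        specificity(cc)    # minority class here is "normal"
    }
    expect_gte(recall(mBal), recall(mUnb))
})

test_that("the score is exactly the affine form x0 + sum(x_i * I_i)", {
    model <- methods::new("CDAIModel", intercept = 0,
                          coefficients = setNames(numeric(3), c("a", "b", "c")),
                          featureIds = c("a", "b", "c"), threshold = 0)
    expect_equal(cdaiScore(model, c(a = 5, b = 5, c = 5)), 0)

    m2 <- methods::new("CDAIModel", intercept = -1,
                       coefficients = c(a = 2, b = 0, c = 0),
                       featureIds = c("a", "b", "c"), threshold = 0)
    expect_equal(cdaiScore(m2, c(a = 0.5, b = 9, c = -3)), 0)

    set.seed(4)
    coefs <- rnorm(20)
    names(coefs) <- sprintf("f%02d", 1:20)
    m3 <- methods::new("CDAIModel", intercept = rnorm(1),
                       coefficients = coefs, featureIds = names(coefs),
                       threshold = 0)
    v <- setNames(rnorm(20), names(coefs))
    expect_equal(cdaiScore(m3, v),
                 m3@intercept + sum(coefs * v), tolerance = 1e-12)

    ## named vectors are reordered; missing enter as zero
    vPerm <- v[sample(20)]
    expect_equal(cdaiScore(m3, vPerm), cdaiScore(m3, v))
    vNA <- v; vNA[3] <- NA
    expect_equal(cdaiScore(m3, vNA),
                 m3@intercept + sum(coefs[-3] * v[-3]), tolerance = 1e-12)
    expect_error(cdaiScore(m3, c(x = 1)), "feature")
})

test_that("score linearity holds for aligned vectors", {
    set.seed(5)
    coefs <- setNames(rnorm(6), paste0("f", 1:6))
    model <- methods::new("CDAIModel", intercept = 1.5, coefficients = coefs,
                          featureIds = names(coefs), threshold = 0)
    v <- setNames(rnorm(6), names(coefs))
    w <- setNames(rnorm(6), names(coefs))
    a <- 2.3; b <- -0.7
    lhs <- cdaiScore(model, a * v + b * w)
    rhs <- a * cdaiScore(model, v) + b * cdaiScore(model, w) -
        (a + b - 1) * model@intercept
    expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("threshold-zero decisions: positive, negative and exact tie", {
    expect_equal(cdaiClassify(3.2), "cancer")
    expect_equal(cdaiClassify(-0.01), "normal")
    expect_equal(cdaiClassify(0), "cancer")   # ties go to cancer
    expect_equal(cdaiClassify(c(1, -1, 0)), c("cancer", "normal", "cancer"))
    expect_error(cdaiClassify(Inf), "finite")
})

test_that("cross-validation on a separable cohort is perfect with zero-width CI", {
    toy <- makeToyCohort(nMet = 60, classes = c("normal", "lungX"),
                         perClass = 14, nAffected = 25, effectSize = 2,
                         dropoutRate = 0, noiseSd = 0.05, seed = 99)
    m <- sampleMatrix(toy$se)
    y <- ifelse(classLabels(toy$se) == "normal", "normal", "cancer")
    cv <- suppressWarnings(crossValidateCDAI(m, y, nSplits = 10, seed = 1))
    expect_equal(cv$summary$mean[cv$summary$metric == "sensitivity"], 100)
    expect_equal(cv$summary$mean[cv$summary$metric == "specificity"], 100)
    expect_equal(cv$summary$ci_lower, cv$summary$ci_upper)
    expect_equal(nrow(cv$perSplit), 10)
    ## CI bounds bracket the mean
    expect_true(all(cv$summary$ci_lower <= cv$summary$mean + 1e-9 &
                        cv$summary$mean <= cv$summary$ci_upper + 1e-9))
})
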