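test_that("prevalence filter removes rare features and keeps a report", {
    m <- matrix(NA_real_, 10, 3,
                dimnames = list(sprintf("S%02d", 1:10), c("a", "b", "c")))
    m[, "a"] <- 1                        # prevalence 1
    m[1:4, "b"] <- 2                     # prevalence 0.4
    ## c never observed -> removed even at low thresholds
    out <- filterFeatures(m, 0.1)
    expect_equal(colnames(out), c("a", "b"))
    expect_equal(attr(out, "removed"), "c")

    out5 <- filterFeatures(m, 0.5)
    expect_equal(colnames(out5), "a")

    ## threshold 0 is the identity
    expect_equal(colnames(filterFeatures(m, 0)), c("a", "b", "c"))
    expect_error(filterFeatures(m[, 3, drop = FALSE], 0.5), "removed all")
})

test_that("quantile reference equals positionwise means of sorted samples", {
    m <- rbind(c(1, 2, 3), c(4, 5, 6))
    colnames(m) <- c("f1", "f2", "f3"); rownames(m) <- c("s1", "s2")
    q <- quantileFit(m)
    expect_equal(q@referenceQuantiles, c(2.5, 3.5, 4.5))

    ## two identical samples -> the common sorted vector
    m2 <- rbind(c(3, 1, 2), c(3, 1, 2))
    dimnames(m2) <- dimnames(m)
    expect_equal(quantileFit(m2)@referenceQuantiles, c(1, 2, 3))

    ## random toy vs independent sort/average oracle
    set.seed(10)
    m3 <- matrix(rnorm(20), 5, 4,
                 dimnames = list(paste0("s", 1:5), paste0("f", 1:4)))
    expect_equal(quantileFit(m3)@referenceQuantiles, oracleQuantileFit(m3),
                 tolerance = 1e-12)

    expect_warning(quantileFit(m[1, , drop = FALSE]), "single-sample")
})

test_that("quantile apply substitutes reference values at within-sample ranks", {
    q <- methods::new("QuantileReference",
                      referenceQuantiles = c(2.5, 3.5, 4.5), nFeatures = 3L)
    expect_equal(quantileApply(c(9, 7, 8), q), c(4.5, 2.5, 3.5))
    ## a sample already on the reference maps to itself
    expect_equal(quantileApply(c(2.5, 3.5, 4.5), q), c(2.5, 3.5, 4.5))
    ## ties get the mean of the spanned reference values
    set.seed(11)
    ref <- sort(rnorm(6))
    q6 <- methods::new("QuantileReference", referenceQuantiles = ref,
                       nFeatures = 6L)
    v <- c(5, 1, 1, 3, 3, 3)
    expect_equal(quantileApply(v, q6), oracleQuantileApply(v, ref),
                 tolerance = 1e-12)
    expect_error(quantileApply(rep(NA_real_, 3), q), "all-missing")
})

test_that("quantile apply is idempotent and missing-aware", {
    set.seed(12)
    m <- matrix(rnorm(40), 8, 5,
                dimnames = list(paste0("s", 1:8), paste0("f", 1:5)))
    q <- quantileFit(m)
    once <- quantileApply(m, q)
    expect_equal(quantileApply(once, q), once, tolerance = 1e-12)

    v <- c(2, NA, 5, 1, NA)
    out <- quantileApply(v, q)
    expect_true(all(is.na(out[c(2, 5)])))
    expect_equal(order(out[c(1, 3, 4)]), order(v[c(1, 3, 4)]))
})

test_that("log10 transform handles pseudocounts and inverts numerically", {
    m <- matrix(c(1000, 0, 10, NA), 2, 2,
                dimnames = list(c("s1", "s2"), c("f1", "f2")))
    expect_error(log10Transform(m, pseudocount = 0), "positive pseudocount")
    out1 <- log10Transform(m, pseudocount = 1)
    expect_equal(out1["s2", "f1"], 0)
    expect_equal(log10Transform(matrix(1000, 1, 1,
                                       dimnames = list("s", "f")), 0)[1, 1], 3)
    expect_true(is.na(out1["s2", "f2"]))

    set.seed(13)
    m2 <- matrix(10^runif(30, 2, 7), 5, 6,
                 dimnames = list(paste0("s", 1:5), paste0("f", 1:6)))
    tr <- log10Transform(m2, pseudocount = 0.5)
    back <- 10^unclass(tr) - 0.5
    attr(back, "pseudocount") <- NULL
    expect_equal(back, m2, tolerance = 1e-12)

    expect_error(log10Transform(matrix(-1, 1, 1)), "negative")
})

test_that("standard scaling standardizes training data and flags constants", {
    set.seed(14)
    m <- matrix(rnorm(50, 10, 3), 10, 5,
                dimnames = list(paste0("s", 1:10), paste0("f", 1:5)))
    m[, 5] <- 7                           # constant feature
    st <- scaleFit(m)
    expect_equal(st@zeroVariance, "f5")
    sc <- scaleApply(m, st)
    expect_equal(unname(colMeans(sc)), rep(0, 5), tolerance = 1e-12)
    expect_equal(unname(apply(sc[, 1:4], 2, sd)), rep(1, 4), tolerance = 1e-12)
    expect_equal(unname(sc[, 5]), rep(0, 10))

    ## held-out row matches the hand computation
    v <- matrix(rnorm(5, 10, 3), 1, 5, dimnames = list("t", paste0("f", 1:5)))
    got <- scaleApply(v, st)
    sds <- st@sds; sds[sds == 0] <- 1
    expect_equal(unname(got[1, ]), unname((v[1, ] - st@means) / sds),
                 tolerance = 1e-12)

    vBad <- matrix(1, 1, 1, dimnames = list("t", "zz"))
    expect_error(scaleApply(vBad, st), "absent")
})

test_that("KNN imputation fills from nearest rows and matches the exhaustive oracle", {
    ## 3-row toy, one missing cell, k = 2
    m <- rbind(s1 = c(1, 2, 3), s2 = c(1.1, 2.1, NA), s3 = c(5, 6, 7))
    colnames(m) <- c("f1", "f2", "f3")
    out <- knnImpute(m, k = 2)
    expect_equal(out["s2", "f3"], mean(c(3, 7)))  # the only two candidates

    set.seed(15)
    m2 <- matrix(rnorm(100), 10, 10,
                 dimnames = list(paste0("s", 1:10), paste0("f", 1:10)))
    m2[sample(100, 15)] <- NA
    if (any(rowSums(!is.na(m2)) == 0)) m2[1, 1] <- 0
    got <- knnImpute(m2, k = 5)
    want <- oracleKnnImpute(m2, k = 5)
    expect_equal(got, want, tolerance = 1e-12)

    ## observed cells never altered
    obs <- !is.na(m2)
    expect_identical(got[obs], m2[obs])
})

test_that("imputation policies: identity without missingness, selective leaves rows of other pools untouched", {
    m <- matrix(1:12, 4, 3, dimnames = list(paste0("s", 1:4), paste0("f", 1:3)))
    storage.mode(m) <- "double"
    expect_identical(knnImpute(m, policy = "uniform"), m)
    expect_identical(knnImpute(m, policy = "selective",
                               labels = c("a", "a", "b", "b")), m)

    ## selective: each class imputed only from its own rows
    m2 <- rbind(a1 = c(1, 2, 3), a2 = c(1, 2, NA), a3 = c(1, 2, 5),
                b1 = c(100, 200, 300), b2 = c(100, 200, 400))
    colnames(m2) <- paste0("f", 1:3)
    out <- suppressWarnings(knnImpute(m2, k = 2, policy = "selective",
                                      labels = c("a", "a", "a", "b", "b")))
    expect_equal(out["a2", "f3"], mean(c(3, 5)))   # never uses the b rows

    expect_error(knnImpute(m2, policy = "selective"), "label")
    expect_error(knnImpute(rbind(c(NA, NA)), k = 1), "no observed")
    expect_warning(knnImpute(rbind(s1 = c(1, NA), s2 = c(1, 2)), k = 5),
                   "fewer than k")
})

test_that("TOOAI recipe leaves test rows non-imputed; CDAI recipe imputes everything", {
    toy <- makeToyCohort(seed = 77)
    m <- sampleMatrix(toy$se)
    tr <- seq_len(nrow(m)) %% 2 == 0
    labs <- classLabels(toy$se)[tr]
    prep <- suppressWarnings(tooaiPrepFit(m[tr, ], labs))
    testOut <- tooaiPrepApply(prep, m[!tr, ])
    ## missing cells in test rows stay missing (non-imputed contract)
    sharedMissing <- is.na(m[!tr, prep$features])
    expect_true(all(is.na(testOut[sharedMissing])))

    cprep <- cdaiPrepFit(m[tr, ])
    expect_false(anyNA(cprep$train))
    ctest <- cdaiPrepApply(cprep, m[!tr, ])
    expect_false(anyNA(ctest))
})
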