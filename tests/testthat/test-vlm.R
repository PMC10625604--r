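test_that("box windows follow the ppm definition", {
    ref <- data.frame(metabolite_id = c("A", "B"),
                      monoisotopic_mass = c(500, 66.7))
    bs <- buildBoxes(ref, 5)
    b <- boxTable(bs)
    expect_equal(b$center_mass, c(66.7, 500))     # sorted by mass
    i500 <- which(b$center_mass == 500)
    expect_equal(b$mass_low[i500], 499.9975)
    expect_equal(b$mass_high[i500], 500.0025)
    i667 <- which(b$center_mass == 66.7)
    expect_equal(b$mass_high[i667] - b$center_mass[i667], 0.0003335)

    expect_error(buildBoxes(ref[0, ], 5), "empty")
    expect_error(buildBoxes(ref, 0), "tolPpm")
})

test_that("overlapping windows are flagged, matching brute-force enumeration", {
    set.seed(1)
    mass <- sort(runif(40, 100, 110))   # crowded -> some overlaps
    ref <- data.frame(metabolite_id = sprintf("M%02d", 1:40),
                      monoisotopic_mass = mass)
    bs <- buildBoxes(ref, 50)           # wide windows force overlaps
    b <- boxTable(bs)
    brute <- list()
    for (i in 1:39) for (j in (i + 1):40) {
        if (b$mass_low[j] <= b$mass_high[i] && b$mass_low[i] <= b$mass_high[j])
            brute[[length(brute) + 1]] <- c(b$box_id[i], b$box_id[j])
    }
    got <- boxOverlaps(bs)
    expect_equal(nrow(got), length(brute))
    if (length(brute)) {
        bm <- do.call(rbind, brute)
        expect_setequal(paste(got$box_id_1, got$box_id_2),
                        paste(bm[, 1], bm[, 2]))
    }

    ## two masses 6 ppm apart at tol 5 -> windows overlap and are flagged
    ref2 <- data.frame(metabolite_id = c("X", "Y"),
                       monoisotopic_mass = c(500, 500 * (1 + 6e-6)))
    expect_equal(nrow(boxOverlaps(buildBoxes(ref2, 5))), 1)
})

test_that("peak assignment: containment, rejection, tie-break", {
    ref <- data.frame(metabolite_id = c("A", "B"),
                      monoisotopic_mass = c(200, 200 * (1 + 6e-6)))
    bs <- buildBoxes(ref, 5)
    ## peak exactly at the lower box center
    a <- assignPeaks(data.frame(mz = 200, intensity = 7), bs)
    expect_equal(unname(a["B00001"]), 7)
    ## peak 10 ppm from the nearest center at tol 5 -> unassigned
    far <- assignPeaks(data.frame(mz = 200 * (1 + 16e-6), intensity = 1), bs)
    expect_equal(length(far), 0)
    expect_equal(attr(far, "unmatched"), 1)
    ## equidistant in ppm between two overlapping boxes -> lower-mass box;
    ## masses 100 and 300 with a peak at 150 give exactly representable
    ## relative deviations of 0.5 on both sides
    refTie <- data.frame(metabolite_id = c("L", "H"),
                         monoisotopic_mass = c(100, 300))
    bsTie <- buildBoxes(refTie, 6e5)   # windows wide enough to overlap at 150
    tie <- assignPeaks(data.frame(mz = 150, intensity = 2), bsTie)
    expect_equal(names(tie), "B00001")
    ## multiple peaks in one box keep the max intensity
    multi <- assignPeaks(data.frame(mz = c(200, 200.0000001),
                                    intensity = c(3, 9)), bs)
    expect_equal(unname(multi["B00001"]), 9)
})

test_that("assignment matches the brute-force nearest-ppm oracle on random peaks", {
    ref <- generateReference(200, seed = 21)
    bs <- buildBoxes(ref, 5)
    set.seed(22)
    ## mix of near-box and random m/z values
    mz <- c(ref$monoisotopic_mass[sample(200, 300, TRUE)] *
                (1 + rnorm(300, 0, 4e-6)),
            runif(200, 66.7, 1000))
    for (z in mz) {
        got <- assignPeaks(data.frame(mz = z, intensity = 1), bs)
        want <- oracleAssign(z, bs)
        if (is.na(want)) expect_equal(length(got), 0)
        else expect_equal(names(got), want)
    }
})

test_that("assignment is independent of peak order", {
    ref <- generateReference(50, seed = 31)
    bs <- buildBoxes(ref, 5)
    set.seed(32)
    peaks <- data.frame(mz = ref$monoisotopic_mass[sample(50, 120, TRUE)] *
                            (1 + rnorm(120, 0, 3e-6)),
                        intensity = runif(120, 1e4, 1e6))
    a <- assignPeaks(peaks, bs)
    perm <- peaks[sample(nrow(peaks)), ]
    b <- assignPeaks(perm, bs)
    expect_identical(a[order(names(a))], b[order(names(b))])
})

test_that("matrix assembly takes the union of observed boxes with missing cells", {
    asg <- list(SA = c(B1 = 10, B2 = 20), SB = c(B2 = 5, B3 = 7))
    se <- assembleMatrix(asg, c("cancer", "normal"), c(1, 1))
    expect_s4_class(se, "MCEDExperiment")
    expect_equal(dim(se), c(3L, 2L))
    expect_equal(sum(missingMask(se)), 2)
    m <- intensityMatrix(se)
    expect_equal(m["B2", "SA"], 20)
    expect_true(is.na(m["B3", "SA"]))

    full <- assembleMatrix(list(S1 = c(B1 = 1, B2 = 2, B3 = 3),
                                S2 = c(B1 = 4, B2 = 5, B3 = 6)),
                           c("cancer", "normal"), c(1, 2))
    expect_equal(sum(missingMask(full)), 0)

    dup <- list(S1 = c(B1 = 1), S1 = c(B1 = 2))
    expect_error(assembleMatrix(dup, c("a", "b"), c(1, 1)), "unique")
})

test_that("planted features all appear as matrix columns after alignment", {
    toy <- makeToyCohort(nMet = 60, perClass = 6, seed = 55)
    planted <- unique(unlist(lapply(toy$profiles, function(p) names(p$effects))))
    b <- boxTable(toy$boxes)
    plantedBoxes <- b$box_id[match(planted, b$metabolite_id)]
    endo <- toy$reference$metabolite_id[toy$reference$origin_flag == "endogenous"]
    plantedBoxes <- plantedBoxes[planted %in% endo]
    expect_true(all(plantedBoxes %in% rownames(toy$se)))
})

test_that("trimming keeps exactly the endogenous features", {
    ref <- data.frame(metabolite_id = sprintf("M%02d", 1:10),
                      monoisotopic_mass = seq(100, 900, length.out = 10),
                      origin_flag = c(rep("endogenous", 7), "drug", "drug",
                                      "plant"))
    bs <- buildBoxes(ref, 5)
    asg <- lapply(1:2, function(i)
        setNames(runif(10), boxTable(bs)$box_id))
    names(asg) <- c("S1", "S2")
    se <- assembleMatrix(asg, c("cancer", "normal"), c(1, 1), boxes = bs)
    trimmed <- trimMatrix(se, ref)
    expect_equal(nrow(trimmed), 7)
    expect_equal(ncol(trimmed), 2)

    allEndo <- ref; allEndo$origin_flag <- "endogenous"
    expect_equal(nrow(trimMatrix(se, allEndo)), 10)

    expect_error(trimMatrix(se, ref[1:5, ]), "not resolvable")
})

test_that("alignment recovers planted peaks into their true boxes at low ppm error", {
    ref <- generateReference(150, seed = 61)
    prof <- makeClassProfiles(ref, "normal", nAffected = 0, seed = 1)
    cfg <- cohortConfig(c(normal = 10), ppmErrorSd = 5 / 3, dropoutRate = 0.1,
                        seed = 62)
    cohort <- generateCohort(ref, prof, cfg)
    bs <- buildBoxes(ref, 5)
    se <- alignCohort(cohort$peaks, cohort$truth, bs)
    recovered <- sum(!missingMask(se))
    expect_gte(recovered / nrow(cohort$peaks), 0.99)
})
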