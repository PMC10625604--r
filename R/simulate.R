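## Synthetic cohort generator: peak lists with the statistical structure the
## pipeline assumes (class-specific intensity shifts, ppm-scale mass error,
## batch drift, dropout) plus ground-truth tables.

#' Generate a synthetic metabolite mass reference
#'
#' Stands in for an HMDB-style lookup: unique metabolite ids with
#' monoisotopic masses drawn uniformly inside the instrument scan range and
#' an origin flag used by [trimMatrix()] (endogenous metabolites are kept;
#' drug- and plant-derived ones are removed).
#'
#' @param nMetabolites number of reference entries (>= 1).
#' @param massLow,massHigh scan range bounds in Da (default 66.7-1000, the
#'   instrument scan range).
#' @param drugFrac,plantFrac expected fraction of entries flagged
#'   drug-/plant-derived (defaults 0.1 each).
#' @param seed integer; fixes the table bit-exactly.
#' @return data.frame with columns `metabolite_id`, `name`,
#'   `monoisotopic_mass`, `origin_flag`, sorted by mass.
#' @examples
#' ref <- generateReference(100, seed = 1)
#' range(ref$monoisotopic_mass)
#' @export
generateReference <- function(nMetabolites, massLow = 66.7, massHigh = 1000,
                              drugFrac = 0.1, plantFrac = 0.1, seed = 1) {
    if (nMetabolites < 1) stop("nMetabolites must be >= 1")
    if (!(massLow > 0 && massHigh > massLow))
        stop("invalid mass range: need 0 < massLow < massHigh")
    if (drugFrac < 0 || plantFrac < 0 || drugFrac + plantFrac > 1)
        stop("origin fractions must be nonnegative and sum to <= 1")
    withr_seed(seed)
    mass <- sort(runif(nMetabolites, massLow, massHigh))
    id <- sprintf("M%05d", seq_len(nMetabolites))
    flag <- sample(c("endogenous", "drug", "plant"), nMetabolites,
                   replace = TRUE,
                   prob = c(1 - drugFrac - plantFrac, drugFrac, plantFrac))
    data.frame(metabolite_id = id,
               name = paste0("metabolite_", id),
               monoisotopic_mass = mass,
               origin_flag = flag,
               stringsAsFactors = FALSE)
}

## Localized seeding: sets the seed and registers an on.exit handler in the
## calling function that restores the caller's RNG state (the saved state is
## embedded in the handler expression by value).
withr_seed <- function(seed) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) {
        old <- get(".Random.seed", envir = globalenv())
        expr <- bquote(assign(".Random.seed", .(old), envir = globalenv()))
        ## prepend so that with repeated calls the outermost saved state is
        ## the one finally restored
        do.call(on.exit, list(expr, add = TRUE, after = FALSE),
                envir = parent.frame())
    }
    set.seed(seed)
    invisible(NULL)
}

#' Build class-effect profiles for the cohort generator
#'
#' Each cancer class perturbs `nAffected` reference metabolites by
#' `effectSize` on the log10 intensity scale; the `"normal"` class carries
#' all-zero shifts by convention.
#'
#' @param reference reference table from [generateReference()].
#' @param classLabels character vector of class labels; must include
#'   `"normal"` if normals are simulated.
#' @param nAffected number of shifted metabolites per cancer class.
#' @param effectSize log10 fold shift applied to affected metabolites.
#' @param seed integer seed for choosing affected metabolites.
#' @return Named list of profiles, each `list(class_label, effects)` with
#'   `effects` a named numeric vector of log10 shifts.
#' @export
makeClassProfiles <- function(reference, classLabels, nAffected = 30,
                              effectSize = 0.5, seed = 1) {
    if (nAffected > nrow(reference))
        stop("nAffected exceeds the number of reference metabolites")
    withr_seed(seed)
    profiles <- lapply(classLabels, function(lab) {
        eff <- setNames(numeric(0), character(0))
        if (lab != "normal" && nAffected > 0) {
            ids <- sample(reference$metabolite_id, nAffected)
            eff <- setNames(rep(effectSize, nAffected), ids)
        }
        list(class_label = lab, effects = eff)
    })
    names(profiles) <- classLabels
    profiles
}

#' Cohort generator configuration
#'
#' Bundles the simulation parameters with validation. `ppmErrorSd` defaults
#' to 5 ppm, the instrument-level mass accuracy; `scanRange` clips perturbed
#' m/z values to the acquisition window.
#'
#' @param samplesPerClass named integer vector, samples per class label.
#' @param nBatches number of acquisition batches (samples assigned
#'   round-robin).
#' @param ppmErrorSd standard deviation of the multiplicative mass error, in
#'   ppm.
#' @param batchShiftSd standard deviation of the per-batch log10 intensity
#'   shift.
#' @param dropoutRate probability in `[0,1]` that a (sample, metabolite)
#'   peak is not observed.
#' @param dropoutDependence logistic slope tying dropout to (low) log10
#'   intensity; 0 = missing completely at random.
#' @param intensityNoiseSd per-observation log10 intensity noise sd.
#' @param scanRange length-2 numeric, m/z clipping bounds in Da.
#' @param seed integer; fixes the full cohort bit-exactly.
#' @return A validated list of class `"cohortConfig"`.
#' @export
cohortConfig <- function(samplesPerClass, nBatches = 3L, ppmErrorSd = 5,
                         batchShiftSd = 0.05, dropoutRate = 0.1,
                         dropoutDependence = 0, intensityNoiseSd = 0.2,
                         scanRange = c(66.7, 1000), seed = 1L) {
    if (is.null(names(samplesPerClass)) || any(names(samplesPerClass) == ""))
        stop("samplesPerClass must be a named vector of class counts")
    if (any(samplesPerClass < 0)) stop("sample counts must be >= 0")
    if (dropoutRate < 0 || dropoutRate > 1)
        stop("dropoutRate must lie in [0, 1]")
    if (nBatches < 1) stop("nBatches must be >= 1")
    if (ppmErrorSd < 0 || batchShiftSd < 0 || intensityNoiseSd < 0)
        stop("standard deviations must be >= 0")
    if (length(scanRange) != 2 || scanRange[1] >= scanRange[2])
        stop("scanRange must be increasing bounds")
    structure(list(samplesPerClass = samplesPerClass,
                   nBatches = as.integer(nBatches), ppmErrorSd = ppmErrorSd,
                   batchShiftSd = batchShiftSd, dropoutRate = dropoutRate,
                   dropoutDependence = dropoutDependence,
                   intensityNoiseSd = intensityNoiseSd,
                   scanRange = scanRange, seed = as.integer(seed)),
              class = "cohortConfig")
}

#' Generate a synthetic peak-list cohort with ground truth
#'
#' For every sample and every non-dropped metabolite one peak is emitted:
#' its m/z is the true monoisotopic mass times `(1 + eps)` with
#' `eps ~ N(0, ppmErrorSd * 1e-6)` (clipped to the scan range), and its
#' log10 intensity is a metabolite baseline plus the class effect, a batch
#' shift, and observation noise. Dropout removes each (sample, metabolite)
#' peak independently with probability `dropoutRate`, optionally weighted
#' towards low intensities via a logistic term.
#'
#' @param reference reference table from [generateReference()].
#' @param profiles class-effect profiles from [makeClassProfiles()]; every
#'   label with a positive sample count must have one.
#' @param config a [cohortConfig()].
#' @param batchSeed optional integer: redraw only the batch-level intensity
#'   shifts under this seed while keeping everything else fixed by
#'   `config$seed` (used by the repeated-run robustness harness).
#' @return `list(peaks, truth)`: `peaks` is a data.frame with columns
#'   `sample_id`, `batch_id`, `rt_seconds`, `mz`, `intensity`; `truth` has
#'   `sample_id`, `class_label`, `batch_id`.
#' @examples
#' ref <- generateReference(50, seed = 1)
#' prof <- makeClassProfiles(ref, c("normal", "breast"), nAffected = 5)
#' cfg <- cohortConfig(c(normal = 4, breast = 4), seed = 7)
#' cohort <- generateCohort(ref, prof, cfg)
#' head(cohort$truth)
#' @export
generateCohort <- function(reference, profiles, config, batchSeed = NULL) {
    stopifnot(inherits(config, "cohortConfig"))
    counts <- config$samplesPerClass[config$samplesPerClass > 0]
    absent <- setdiff(names(counts), names(profiles))
    if (length(absent))
        stop("no class-effect profile for label(s): ",
             paste(absent, collapse = ", "))
    badIds <- unlist(lapply(profiles, function(p)
        setdiff(names(p$effects), reference$metabolite_id)))
    if (length(badIds))
        stop("profile effects reference unknown metabolite ids: ",
             paste(unique(badIds), collapse = ", "))

    nMet <- nrow(reference)
    labels <- rep(names(counts), counts)
    nSamp <- length(labels)
    sampleIds <- sprintf("S%04d", seq_len(nSamp))
    batch <- ((seq_len(nSamp) - 1L) %% config$nBatches) + 1L

    withr_seed(config$seed)
    ## per-metabolite log10 baseline and retention time (stable across runs
    ## that share config$seed)
    baseline <- runif(nMet, 4.5, 7)
    rtTrue <- runif(nMet, 30, 840)

    ## class shift matrix: metabolites x classes
    shift <- matrix(0, nMet, length(counts),
                    dimnames = list(reference$metabolite_id, names(counts)))
    for (lab in names(counts)) {
        eff <- profiles[[lab]]$effects
        if (length(eff)) shift[names(eff), lab] <- eff
    }

    ## observation-level draws, samples x metabolites
    noise <- matrix(rnorm(nSamp * nMet, 0, config$intensityNoiseSd),
                    nSamp, nMet)
    eps <- matrix(rnorm(nSamp * nMet, 0, config$ppmErrorSd * 1e-6),
                  nSamp, nMet)
    rtJit <- matrix(rnorm(nSamp * nMet, 0, 2), nSamp, nMet)
    dropU <- matrix(runif(nSamp * nMet), nSamp, nMet)

    ## batch shifts drawn last so they can be redrawn independently
    if (!is.null(batchSeed)) withr_seed(batchSeed)
    batchShift <- rnorm(config$nBatches, 0, config$batchShiftSd)

    logI <- matrix(baseline, nSamp, nMet, byrow = TRUE) +
        t(shift[, labels, drop = FALSE]) + batchShift[batch] + noise

    if (config$dropoutDependence == 0) {
        drop <- dropU < config$dropoutRate
    } else {
        ## dropout odds increase for intensities below the baseline midline
        center <- mean(baseline)
        p <- plogis(qlogis(pmin(pmax(config$dropoutRate, 1e-12), 1 - 1e-12)) -
                        config$dropoutDependence * (logI - center))
        drop <- dropU < p
    }

    mz <- matrix(reference$monoisotopic_mass, nSamp, nMet, byrow = TRUE) *
        (1 + eps)
    mz <- pmin(pmax(mz, config$scanRange[1]), config$scanRange[2])
    rt <- matrix(rtTrue, nSamp, nMet, byrow = TRUE) + rtJit

    keep <- which(!drop)
    si <- ((keep - 1L) %% nSamp) + 1L   # row (sample) index
    peaks <- data.frame(sample_id = sampleIds[si],
                        batch_id = batch[si],
                        rt_seconds = rt[keep],
                        mz = mz[keep],
                        intensity = 10^logI[keep],
                        stringsAsFactors = FALSE)
    peaks <- peaks[order(peaks$sample_id, peaks$mz), , drop = FALSE]
    rownames(peaks) <- NULL
    truth <- data.frame(sample_id = sampleIds, class_label = labels,
                        batch_id = batch, stringsAsFactors = FALSE)
    list(peaks = peaks, truth = truth)
}

#' Canonical class labels for the 15-cancer detection problem
#'
#' The fifteen tissue-of-origin classes handled by the multiclass tier, plus
#' `"normal"` when `includeNormal` is set; used as the default label set for
#' demo cohorts.
#'
#' @param includeNormal prepend the `"normal"` control label.
#' @return Character vector of class labels.
#' @export
tissueClasses <- function(includeNormal = FALSE) {
    classes <- c("breast", "endometrial", "cervical", "ovarian", "lung",
                 "AML", "thyroid", "melanoma", "colorectal", "kidney",
                 "NHL", "pancreatic", "head_neck", "gastric", "liver_bile")
    if (includeNormal) c("normal", classes) else classes
}
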