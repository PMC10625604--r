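## Virtual lock-mass (VLM) alignment: ppm-tolerance mass windows anchored on
## the metabolite reference, peak-to-box assignment, matrix assembly and
## origin-flag trimming.

#' Build VLM boxes from a metabolite reference
#'
#' One mass window per reference metabolite, centered on its monoisotopic
#' mass with half-width `tolPpm` parts per million, so window width grows
#' proportionally with mass (mass errors increase with increasing mass).
#' Pairs of windows that intersect (reference masses closer than about
#' 2*tolPpm) are reported in the overlap table.
#'
#' @param reference data.frame with `metabolite_id` and `monoisotopic_mass`.
#' @param tolPpm window half-width in ppm (> 0; default 5, the instrument
#'   mass accuracy).
#' @return A [VLMBoxSet-class].
#' @examples
#' ref <- data.frame(metabolite_id = "M1", monoisotopic_mass = 500)
#' boxTable(buildBoxes(ref))  # window (499.9975, 500.0025)
#' @export
buildBoxes <- function(reference, tolPpm = 5) {
    if (tolPpm <= 0) stop("tolPpm must be > 0")
    if (is.null(reference) || nrow(reference) == 0)
        stop("reference table is empty")
    ord <- order(reference$monoisotopic_mass, reference$metabolite_id)
    center <- reference$monoisotopic_mass[ord]
    boxes <- data.frame(
        box_id = sprintf("B%05d", seq_along(ord)),
        metabolite_id = reference$metabolite_id[ord],
        center_mass = center,
        mass_low = center * (1 - tolPpm * 1e-6),
        mass_high = center * (1 + tolPpm * 1e-6),
        stringsAsFactors = FALSE)
    ## overlapping pairs among mass-sorted windows: sweep forward while the
    ## next window's low edge is inside the current window
    ov <- list()
    n <- nrow(boxes)
    for (i in seq_len(max(0, n - 1))) {
        j <- i + 1L
        while (j <= n && boxes$mass_low[j] <= boxes$mass_high[i]) {
            ov[[length(ov) + 1L]] <- c(boxes$box_id[i], boxes$box_id[j])
            j <- j + 1L
        }
    }
    overlaps <- if (length(ov)) {
        m <- do.call(rbind, ov)
        data.frame(box_id_1 = m[, 1], box_id_2 = m[, 2],
                   stringsAsFactors = FALSE)
    } else data.frame(box_id_1 = character(0), box_id_2 = character(0),
                      stringsAsFactors = FALSE)
    methods::new("VLMBoxSet", boxes = boxes, tolPpm = tolPpm,
                 overlaps = overlaps)
}

#' Assign one sample's peaks to VLM boxes
#'
#' Each peak is matched to at most one box: among the windows containing its
#' m/z, the one with the smallest absolute ppm deviation from center wins,
#' with exact ties broken toward the lower-mass box. Multiple peaks landing
#' in the same box are aggregated by keeping the maximum intensity, so the
#' result is independent of peak order. Peaks inside no window are counted
#' (attribute `"unmatched"`) but not fatal.
#'
#' @param peaks data.frame with columns `mz` and `intensity` for one sample.
#' @param boxes A [VLMBoxSet-class].
#' @return Named numeric vector (names = box ids) of per-box intensities for
#'   boxes that received at least one peak, with attribute `unmatched`.
#' @export
assignPeaks <- function(peaks, boxes) {
    stopifnot(is(boxes, "VLMBoxSet"))
    if (is.null(peaks) || nrow(peaks) == 0) stop("peak list is empty")
    b <- boxes@boxes
    n <- nrow(b)
    ## candidate windows lie near the insertion point in the sorted centers;
    ## look a few boxes back to cover overlapping windows
    pos <- findInterval(peaks$mz, b$mass_low)
    best <- integer(nrow(peaks))
    bestDev <- rep(Inf, nrow(peaks))
    for (off in 0:3) {
        j <- pos - off
        ok <- j >= 1 & j <= n
        if (!any(ok)) next
        inWin <- ok
        inWin[ok] <- peaks$mz[ok] >= b$mass_low[j[ok]] &
            peaks$mz[ok] <= b$mass_high[j[ok]]
        if (!any(inWin)) next
        dev <- rep(Inf, nrow(peaks))
        dev[inWin] <- abs(peaks$mz[inWin] - b$center_mass[j[inWin]]) /
            b$center_mass[j[inWin]] * 1e6
        ## strict improvement keeps the lower-mass box on exact ppm ties,
        ## because offsets scan from higher- to lower-mass candidates and
        ## ties must favour the later (lower-mass) candidate
        upd <- inWin & (dev < bestDev | (dev == bestDev & j < best))
        best[upd] <- j[upd]
        bestDev[upd] <- dev[upd]
    }
    matched <- best > 0
    out <- numeric(0)
    if (any(matched)) {
        agg <- tapply(peaks$intensity[matched], b$box_id[best[matched]], max)
        out <- setNames(as.numeric(agg), names(agg))
    }
    attr(out, "unmatched") <- sum(!matched)
    out
}

#' Assemble per-sample box assignments into an MCEDExperiment
#'
#' The feature set is the union of boxes observed in at least one sample
#' (in mass order); cells for (sample, box) pairs with no peak are missing.
#'
#' @param assignments named list (names = sample ids) of vectors from
#'   [assignPeaks()].
#' @param labels character, class label per sample (same order).
#' @param batchIds batch id per sample.
#' @param boxes optional [VLMBoxSet-class]; when supplied, box annotation
#'   (metabolite id, center mass) is attached as row metadata.
#' @return An [MCEDExperiment-class], features x samples.
#' @export
assembleMatrix <- function(assignments, labels, batchIds, boxes = NULL) {
    ids <- names(assignments)
    if (is.null(ids) || anyDuplicated(ids))
        stop("assignments must be named with unique sample ids")
    if (length(labels) != length(ids) || length(batchIds) != length(ids))
        stop("labels and batchIds must have one entry per sample")
    feat <- sort(unique(unlist(lapply(assignments, names))))
    if (length(feat) == 0) stop("no box received any peak")
    mat <- matrix(NA_real_, length(feat), length(ids),
                  dimnames = list(feat, ids))
    for (s in ids) {
        a <- assignments[[s]]
        if (length(a)) mat[names(a), s] <- as.numeric(a)
    }
    rd <- NULL
    if (!is.null(boxes)) {
        b <- boxes@boxes
        rd <- b[match(feat, b$box_id),
                c("box_id", "metabolite_id", "center_mass")]
        rownames(rd) <- feat
    }
    MCEDExperiment(mat, labels, batchIds, rowData = rd)
}

#' Align a whole peak-list cohort into a feature matrix
#'
#' Convenience wrapper: runs [assignPeaks()] per sample and
#' [assembleMatrix()] across samples.
#'
#' @param peaks cohort peak table (`sample_id`, `mz`, `intensity`, ...).
#' @param truth per-sample table (`sample_id`, `class_label`, `batch_id`).
#' @param boxes A [VLMBoxSet-class].
#' @return An [MCEDExperiment-class].
#' @export
alignCohort <- function(peaks, truth, boxes) {
    if (anyDuplicated(truth$sample_id)) stop("duplicate sample ids in truth")
    split_idx <- split(seq_len(nrow(peaks)), peaks$sample_id)
    missing <- setdiff(truth$sample_id, names(split_idx))
    if (length(missing))
        stop("samples without any peak: ", paste(missing, collapse = ", "))
    assignments <- lapply(truth$sample_id, function(s)
        assignPeaks(peaks[split_idx[[s]], , drop = FALSE], boxes))
    names(assignments) <- truth$sample_id
    assembleMatrix(assignments, truth$class_label, truth$batch_id, boxes)
}

#' Trim a feature matrix to endogenous metabolites
#'
#' Removes features whose reference entry is flagged drug- or plant-derived,
#' mirroring the removal of drug/plant metabolites from the aligned matrix;
#' sample rows are unchanged.
#'
#' @param x An [MCEDExperiment-class] whose row metadata carries
#'   `metabolite_id` (as produced by [assembleMatrix()] with `boxes`).
#' @param reference reference table with `metabolite_id` and `origin_flag`.
#' @return The trimmed [MCEDExperiment-class].
#' @export
trimMatrix <- function(x, reference) {
    rd <- SummarizedExperiment::rowData(x)
    if (!"metabolite_id" %in% colnames(rd))
        stop("row metadata lacks metabolite_id; assemble with a VLMBoxSet")
    idx <- match(rd$metabolite_id, reference$metabolite_id)
    if (anyNA(idx))
        stop("feature(s) not resolvable in the reference: ",
             paste(utils::head(rd$metabolite_id[is.na(idx)]), collapse = ", "))
    keep <- reference$origin_flag[idx] == "endogenous"
    x[keep, ]
}
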