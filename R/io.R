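## Delimited-text I/O for the pipeline artifacts. Everything is
## tab-separated plain text so runs are diffable and portable.

#' Read / write pipeline tables
#'
#' Thin tab-separated wrappers used for peak lists, truth/label tables,
#' reference tables and reports.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `readTable()`: a data.frame; `writeTable()`: `path`, invisibly.
#' @export
writeTable <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeTable
#' @export
readTable <- function(path) {
    read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read an MCEDExperiment as delimited text
#'
#' The intensity matrix (features x samples) goes to `<stem>.matrix.tsv`
#' with missing cells written as `NA`; sample metadata (class label, batch)
#' to `<stem>.samples.tsv`; feature metadata, if any, to
#' `<stem>.features.tsv`.
#'
#' @param x An [MCEDExperiment-class].
#' @param stem path stem (files get `.matrix.tsv`, `.samples.tsv`,
#'   `.features.tsv` suffixes).
#' @return `writeMCED()`: `stem`, invisibly; `readMCED()`: the
#'   reconstructed [MCEDExperiment-class].
#' @export
writeMCED <- function(x, stem) {
    m <- intensityMatrix(x)
    df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, paste0(stem, ".matrix.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeTable(data.frame(sample_id = colnames(x),
                          class_label = classLabels(x),
                          batch_id = batchIds(x)),
               paste0(stem, ".samples.tsv"))
    rd <- as.data.frame(SummarizedExperiment::rowData(x))
    if (ncol(rd) > 0) {
        rd <- cbind(feature_id = rownames(x), rd)
        writeTable(rd, paste0(stem, ".features.tsv"))
    }
    invisible(stem)
}

#' @rdname writeMCED
#' @export
readMCED <- function(stem) {
    df <- readTable(paste0(stem, ".matrix.tsv"))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$feature_id
    samp <- readTable(paste0(stem, ".samples.tsv"))
    if (!identical(colnames(m), samp$sample_id))
        m <- m[, samp$sample_id, drop = FALSE]
    rd <- NULL
    fpath <- paste0(stem, ".features.tsv")
    if (file.exists(fpath)) {
        rd <- readTable(fpath)
        rownames(rd) <- rd$feature_id
        rd$feature_id <- NULL
        rd <- rd[rownames(m), , drop = FALSE]
    }
    MCEDExperiment(m, samp$class_label, samp$batch_id, rowData = rd)
}

#' Read peak lists from mzML files
#'
#' Optional ingestion of real acquisitions: each mzML file becomes one
#' sample whose centroided peaks are pooled across scans (maximum intensity
#' per m/z within each scan is retained as emitted by the instrument).
#' Requires the `mzR` package.
#'
#' @param files character vector of mzML paths.
#' @param sampleIds sample id per file (default: file name without
#'   extension).
#' @param batchIds batch id per file (default 1).
#' @return Peak table with `sample_id`, `batch_id`, `rt_seconds`, `mz`,
#'   `intensity`.
#' @export
readPeaksMzML <- function(files, sampleIds = NULL, batchIds = 1L) {
    if (!requireNamespace("mzR", quietly = TRUE))
        stop("reading mzML requires the mzR package")
    if (is.null(sampleIds))
        sampleIds <- sub("\\.[^.]+$", "", basename(files))
    batchIds <- rep_len(batchIds, length(files))
    out <- lapply(seq_along(files), function(i) {
        ms <- mzR::openMSfile(files[i])
        on.exit(mzR::close(ms))
        hdr <- mzR::header(ms)
        pk <- mzR::peaks(ms)
        if (is.matrix(pk)) pk <- list(pk)
        do.call(rbind, lapply(seq_along(pk), function(s) {
            if (nrow(pk[[s]]) == 0) return(NULL)
            data.frame(sample_id = sampleIds[i], batch_id = batchIds[i],
                       rt_seconds = hdr$retentionTime[s],
                       mz = pk[[s]][, 1], intensity = pk[[s]][, 2],
                       stringsAsFactors = FALSE)
        }))
    })
    do.call(rbind, out)
}
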