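#' Read a peak table from CSV or XLSX
#'
#' Reads a rectangular LC-MS peak table in which each row is a sample and the
#' columns are: an optional sample-id column, the processing-stage sample-type
#' column, the origin column, and then one numeric column per compound (in the
#' file's compound order, which is preserved). Missing compound cells are
#' treated as peak not detected (0) and counted in a message; non-numeric
#' compound cells and negative peak areas are errors that name the offending
#' sample/compound coordinates.
#'
#' @param path file to read.
#' @param format \code{"csv"} (comma separated, header row) or \code{"xlsx"}
#'   (one sheet, header row; requires the readxl package).
#' @param sheet sheet name for XLSX input.
#' @param sampleIdCol,sampleTypeCol,originCol header names of the metadata
#'   columns. The sample-id column is optional; ids are generated when it is
#'   absent.
#' @return a \code{\linkS4class{PeakTable}}.
#' @seealso \code{\link{writePeakTable}}
#' @export
readPeakTable <- function(path, format = c("csv", "xlsx"),
                          sheet = "lcms_data",
                          sampleIdCol = "sample_id",
                          sampleTypeCol = "sample-type",
                          originCol = "origin") {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    df <- if (format == "csv") {
        utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    } else {
        if (!requireNamespace("readxl", quietly = TRUE))
            stop("XLSX input requires the 'readxl' package")
        as.data.frame(readxl::read_excel(path, sheet = sheet),
                      check.names = FALSE, stringsAsFactors = FALSE)
    }
    for (needed in c(sampleTypeCol, originCol))
        if (!needed %in% colnames(df))
            stop(sprintf("required metadata column '%s' is missing", needed))

    if (sampleIdCol %in% colnames(df)) {
        ids <- as.character(df[[sampleIdCol]])
    } else {
        ids <- sprintf("S%03d", seq_len(nrow(df)))
    }
    if (anyDuplicated(ids)) stop("duplicate sample ids in input")
    stage <- as.character(df[[sampleTypeCol]])
    orig <- as.character(df[[originCol]])
    bad <- is.na(stage) | stage == "" | is.na(orig) | orig == ""
    if (any(bad))
        stop("missing sample-type/origin label for sample(s): ",
             paste(ids[bad], collapse = ", "))

    meta <- c(sampleIdCol, sampleTypeCol, originCol)
    compCols <- setdiff(colnames(df), meta)
    if (!length(compCols)) stop("no compound columns found")
    m <- matrix(NA_real_, nrow(df), length(compCols),
                dimnames = list(ids, compCols))
    for (k in seq_along(compCols)) {
        v <- df[[compCols[k]]]
        if (is.character(v)) {
            v <- trimws(v)
            empty <- v == "" | is.na(v)
            num <- suppressWarnings(as.numeric(v))
            garbled <- !empty & is.na(num)
            if (any(garbled))
                stop(sprintf(
                    "non-numeric peak area for compound '%s', sample(s): %s",
                    compCols[k], paste(ids[garbled], collapse = ", ")))
            num[empty] <- NA_real_
            v <- num
        }
        m[, k] <- as.numeric(v)
    }
    nMissing <- sum(is.na(m))
    if (nMissing > 0) {
        message(nMissing, " missing compound cell(s) set to 0 (not detected)")
        m[is.na(m)] <- 0
    }
    neg <- which(m < 0, arr.ind = TRUE)
    if (nrow(neg))
        stop(sprintf("negative peak area at sample '%s', compound '%s'",
                     rownames(m)[neg[1L, 1L]], colnames(m)[neg[1L, 2L]]))
    PeakTable(m, sampleType = stage, origin = orig, samplesInRows = TRUE)
}

#' Write a peak table to CSV
#'
#' Emits the same rectangular dialect \code{\link{readPeakTable}} consumes:
#' one row per sample with columns \code{sample_id}, \code{sample-type},
#' \code{origin}, then the compounds in table order. Writing an XLSX file is
#' not supported (no writer backend); XLSX is read-only in this package.
#'
#' @param table a \code{\linkS4class{PeakTable}} with at least one compound.
#' @param path output file.
#' @param format only \code{"csv"}.
#' @return invisibly, \code{path}.
#' @export
writePeakTable <- function(table, path, format = "csv") {
    stopifnot(methods::is(table, "PeakTable"))
    format <- match.arg(format, "csv")
    if (nrow(table) == 0L)
        stop("refusing to write a peak table with no compounds")
    a <- t(peakAreas(table))
    out <- data.frame(sample_id = rownames(a),
                      check.names = FALSE, stringsAsFactors = FALSE)
    out[["sample-type"]] <- unname(sampleType(table))
    out[["origin"]] <- unname(origin(table))
    out <- cbind(out, as.data.frame(a, check.names = FALSE))
    utils::write.csv(out, path, row.names = FALSE)
    invisible(path)
}

#' Write a node-attribute table for Cytoscape import
#'
#' One row per sample with its id, processing-stage sample type and origin;
#' the companion file to the edge exports of \code{\link{exportNetwork}}.
#'
#' @param table a \code{\linkS4class{PeakTable}}.
#' @param path output CSV file.
#' @return invisibly, \code{path}.
#' @export
writeNodeAttributes <- function(table, path) {
    stopifnot(methods::is(table, "PeakTable"))
    utils::write.csv(
        data.frame(sample_id = sampleIds(table),
                   sample_type = unname(sampleType(table)),
                   origin = unname(origin(table)),
                   stringsAsFactors = FALSE),
        path, row.names = FALSE)
    invisible(path)
}
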