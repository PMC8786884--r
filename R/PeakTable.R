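#' Construct a PeakTable
#'
#' Builds a \code{\linkS4class{PeakTable}} from a peak-area matrix and the two
#' per-sample attributes. The matrix may be oriented either way; by convention
#' it is passed samples-in-rows (the layout of the tabular files this package
#' reads and writes) and stored compounds-in-rows internally, following the
#' SummarizedExperiment convention.
#'
#' @param peakAreas numeric matrix of nonnegative peak areas, samples in rows
#'   and compounds in columns (set \code{samplesInRows = FALSE} for the
#'   transposed orientation). Row/column names supply sample and compound ids;
#'   defaults are generated when absent.
#' @param sampleType character or factor of processing-stage sample types,
#'   one per sample.
#' @param origin character or factor of origins (e.g. countries), one per
#'   sample.
#' @param samplesInRows logical; orientation of \code{peakAreas}.
#' @return a \code{\linkS4class{PeakTable}}.
#' @examples
#' m <- matrix(runif(12), nrow = 3,
#'             dimnames = list(paste0("S", 1:3), paste0("C", 1:4)))
#' pt <- PeakTable(m, sampleType = c("unfermented", "fermented", "fermented"),
#'                 origin = c("Ghana", "Ghana", "Brazil"))
#' pt
#' @export
PeakTable <- function(peakAreas, sampleType, origin, samplesInRows = TRUE) {
    peakAreas <- as.matrix(peakAreas)
    if (samplesInRows) peakAreas <- t(peakAreas)
    if (is.null(colnames(peakAreas)))
        colnames(peakAreas) <- sprintf("S%03d", seq_len(ncol(peakAreas)))
    if (is.null(rownames(peakAreas)))
        rownames(peakAreas) <- sprintf("compound_%04d", seq_len(nrow(peakAreas)))
    if (length(sampleType) != ncol(peakAreas) ||
        length(origin) != ncol(peakAreas))
        stop("need exactly one sampleType and one origin label per sample")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(peakArea = peakAreas),
        colData = S4Vectors::DataFrame(
            sampleType = as.character(sampleType),
            origin = as.character(origin),
            row.names = colnames(peakAreas)))
    methods::new("PeakTable", se)
}

#' @describeIn PeakTable peak-area matrix, compounds x samples.
#' @param x a PeakTable
#' @export
setMethod("peakAreas", "PeakTable", function(x)
    SummarizedExperiment::assay(x, "peakArea"))

#' @describeIn PeakTable processing-stage sample type per sample (named).
#' @export
setMethod("sampleType", "PeakTable", function(x)
    stats::setNames(SummarizedExperiment::colData(x)$sampleType, colnames(x)))

#' @describeIn PeakTable origin per sample (named).
#' @export
setMethod("origin", "PeakTable", function(x)
    stats::setNames(SummarizedExperiment::colData(x)$origin, colnames(x)))

#' @describeIn PeakTable sample identifiers.
#' @export
setMethod("sampleIds", "PeakTable", function(x) colnames(x))

#' @describeIn PeakTable compound identifiers (assay row names).
#' @export
setMethod("compoundIds", "PeakTable", function(x) rownames(x))

#' @export
#' @describeIn PeakTable compact display.
#' @param object a PeakTable
setMethod("show", "PeakTable", function(object) {
    cat("PeakTable:", ncol(object), "samples x", nrow(object), "compounds\n")
    cat("  sample types:",
        paste(names(table(sampleType(object))), collapse = ", "), "\n")
    cat("  origins:     ",
        paste(names(table(origin(object))), collapse = ", "), "\n")
    s <- colSums(peakAreas(object))
    cat(sprintf("  per-sample sums: [%.4g, %.4g]\n", min(s), max(s)))
})

#' Normalize per-sample peak-area sums
#'
#' Rescales every sample profile so its total peak area equals \code{total}
#' (default 100, making each entry the relative percentage amount of the
#' compound in that sample's LC-MS profile). Column order is unchanged. The
#' operation is idempotent and, being a per-sample positive scaling, preserves
#' the within-sample rank order of compounds, hence leaves Spearman
#' correlations between samples untouched.
#'
#' @param table a \code{\linkS4class{PeakTable}}.
#' @param total positive target sum per sample.
#' @return a normalized \code{\linkS4class{PeakTable}}.
#' @examples
#' pt <- PeakTable(matrix(c(1, 1, 2, 2, 3, 5), nrow = 2, byrow = TRUE),
#'                 sampleType = c("a", "a"), origin = c("x", "y"))
#' colSums(peakAreas(normalizeSampleSums(pt)))
#' @export
normalizeSampleSums <- function(table, total = 100) {
    stopifnot(methods::is(table, "PeakTable"))
    if (!is.numeric(total) || length(total) != 1L || total <= 0)
        stop("'total' must be a positive number")
    a <- peakAreas(table)
    s <- colSums(a)
    if (any(s <= 0))
        stop("cannot normalize sample(s) with all-zero peaks: ",
             paste(colnames(a)[s <= 0], collapse = ", "))
    SummarizedExperiment::assay(table, "peakArea") <-
        sweep(a, 2L, s / total, "/")
    methods::validObject(table)
    table
}

#' Keep the compounds with the largest mean peak area
#'
#' Sorts compounds in descending order of their mean peak area across all
#' samples (ties keep their original relative order) and retains the first
#' \code{n}. On an already-sorted table this is simply the first \code{n}
#' columns of the tabular layout. Restricting analyses to the most abundant
#' compounds (around the top 1000) is the documented fast path for
#' threshold-sweep statistics on large tables.
#'
#' @param table a \code{\linkS4class{PeakTable}}.
#' @param n number of compounds to keep, between 1 and the compound count.
#' @return a \code{\linkS4class{PeakTable}} with \code{n} compounds, sorted by
#'   descending mean peak area.
#' @export
selectTopCompounds <- function(table, n) {
    stopifnot(methods::is(table, "PeakTable"))
    p <- nrow(table)
    if (!is.numeric(n) || length(n) != 1L || n < 1 || n > p || n != round(n))
        stop(sprintf("'n' must be an integer in [1, %d]", p))
    means <- rowMeans(peakAreas(table))
    ord <- order(means, decreasing = TRUE, method = "radix")
    table[ord[seq_len(n)], ]
}

#' Extract one per-sample labelling from a PeakTable
#'
#' Convenience accessor returning the chosen attribute as a named character
#' vector (names = sample ids), the form the network-statistics and
#' classification functions consume.
#'
#' @param table a \code{\linkS4class{PeakTable}}.
#' @param attribute \code{"sampleType"} or \code{"origin"}.
#' @return named character vector of labels.
#' @export
sampleLabels <- function(table, attribute = c("sampleType", "origin")) {
    attribute <- match.arg(attribute)
    if (attribute == "sampleType") sampleType(table) else origin(table)
}
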