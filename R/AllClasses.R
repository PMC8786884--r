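#' PeakTable: an LC-MS peak-area table with sample metadata
#'
#' A \code{PeakTable} stores one LC-MS peak-area (relative concentration)
#' matrix together with the two categorical sample attributes the analysis
#' revolves around: the coarse processing-stage sample type and the finer
#' country of origin. It extends
#' \link[SummarizedExperiment]{SummarizedExperiment}, so compounds are rows of
#' the assay and samples are columns, and the sample attributes live in
#' \code{colData}. All entries must be nonnegative; a table whose per-sample
#' sums equal a common total (conventionally 100, i.e. relative percent) is
#' produced by \code{\link{normalizeSampleSums}}.
#'
#' @seealso \code{\link{PeakTable}} (constructor), \code{\link{peakAreas}},
#'   \code{\link{sampleType}}, \code{\link{origin}},
#'   \code{\link{simulatePeakTable}}, \code{\link{readPeakTable}}
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass PeakTable
setClass("PeakTable", contains = "SummarizedExperiment")

setValidity("PeakTable", function(object) {
    msg <- character()
    if (!"peakArea" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'peakArea' is required")
    else {
        a <- SummarizedExperiment::assay(object, "peakArea")
        if (!is.numeric(a))
            msg <- c(msg, "'peakArea' assay must be numeric")
        else if (anyNA(a))
            msg <- c(msg, "'peakArea' assay must not contain NA")
        else if (any(a < 0))
            msg <- c(msg, "'peakArea' assay must be nonnegative")
    }
    cd <- SummarizedExperiment::colData(object)
    for (fld in c("sampleType", "origin")) {
        if (!fld %in% colnames(cd))
            msg <- c(msg, sprintf("colData column '%s' is required", fld))
        else if (anyNA(cd[[fld]]))
            msg <- c(msg, sprintf("every sample needs a '%s' label", fld))
    }
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "samples must carry unique ids (colnames)")
    if (length(msg)) msg else TRUE
})

#' CorrelationMatrix: pairwise sample-sample correlations
#'
#' Symmetric matrix of pairwise correlations between the LC-MS profiles of all
#' samples in a \code{\link{PeakTable}}, computed with either the Spearman
#' rank correlation or the Pearson correlation. Entries lie in [-1, 1] with a
#' unit diagonal.
#'
#' @slot values symmetric numeric matrix with sample ids as dimnames.
#' @slot method \code{"spearman"} or \code{"pearson"}.
#' @seealso \code{\link{correlationMatrix}}, \code{\link{buildNetwork}}
#' @exportClass CorrelationMatrix
setClass("CorrelationMatrix",
    representation(values = "matrix", method = "character"))

setValidity("CorrelationMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v) || nrow(v) != ncol(v))
        msg <- c(msg, "'values' must be a square numeric matrix")
    else {
        if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
            msg <- c(msg, "'values' needs identical row/column sample ids")
        if (anyNA(v))
            msg <- c(msg, "'values' must not contain NA")
        else {
            if (max(abs(v - t(v))) > 1e-8)
                msg <- c(msg, "'values' must be symmetric")
            if (any(v < -1 - 1e-8) || any(v > 1 + 1e-8))
                msg <- c(msg, "correlations must lie in [-1, 1]")
            if (max(abs(diag(v) - 1)) > 1e-8)
                msg <- c(msg, "diagonal entries must equal 1")
        }
    }
    if (length(object@method) != 1L ||
        !object@method %in% c("spearman", "pearson"))
        msg <- c(msg, "'method' must be 'spearman' or 'pearson'")
    if (length(msg)) msg else TRUE
})

#' ThresholdedNetwork: a correlation network at one threshold
#'
#' Nodes are samples; an (undirected, weighted) edge joins two samples exactly
#' when their correlation is at least the threshold \emph{and} strictly
#' positive. All samples are always retained as nodes; isolation is a derived
#' property (\code{\link{isolatedNodes}}), never a removal, so classification
#' denominators stay explicit.
#'
#' @slot threshold correlation threshold in [0, 1] (\code{NA} for
#'   attribute-defined ideal networks, see \code{\link{idealNetwork}}).
#' @slot method correlation method the weights came from (\code{"spearman"},
#'   \code{"pearson"}, or \code{"ideal"}).
#' @slot nodes character vector of sample ids.
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{weight};
#'   \code{from} precedes \code{to} in node order, no self loops.
#' @seealso \code{\link{buildNetwork}}, \code{\link{sweepNetworks}},
#'   \code{\link{connectedComponents}}, \code{\link{exportNetwork}}
#' @exportClass ThresholdedNetwork
setClass("ThresholdedNetwork",
    representation(threshold = "numeric", method = "character",
                   nodes = "character", edges = "data.frame"))

setValidity("ThresholdedNetwork", function(object) {
    msg <- character()
    th <- object@threshold
    if (length(th) != 1L || (!is.na(th) && (th < 0 || th > 1)))
        msg <- c(msg, "'threshold' must be one value in [0, 1] or NA")
    e <- object@edges
    need <- c("from", "to", "weight")
    if (!all(need %in% colnames(e)))
        msg <- c(msg, "edges need columns from, to, weight")
    else if (nrow(e)) {
        if (!all(e$from %in% object@nodes) || !all(e$to %in% object@nodes))
            msg <- c(msg, "edges must reference known nodes")
        if (any(e$from == e$to))
            msg <- c(msg, "self loops are not allowed")
        if (any(e$weight <= 0))
            msg <- c(msg, "edge weights must be strictly positive")
        if (!is.na(th) && any(e$weight < th))
            msg <- c(msg, "every edge weight must be >= threshold")
    }
    if (anyDuplicated(object@nodes))
        msg <- c(msg, "node ids must be unique")
    if (length(msg)) msg else TRUE
})

#' PredictionGrid: majority-vote outcomes per node and threshold
#'
#' Node-by-threshold matrix of leave-one-out majority-vote outcomes for one
#' sample attribute. A cell is \code{"correct"} or \code{"incorrect"} when the
#' vote among the node's network neighbours is decisive, and
#' \code{"undefined"} when the node has no voters at that threshold or the
#' top vote ties.
#'
#' @slot attribute which attribute was inferred (\code{"sampleType"} or
#'   \code{"origin"}).
#' @slot thresholds the increasing threshold grid (columns).
#' @slot outcomes character matrix, nodes x thresholds, values in
#'   \code{c("correct", "incorrect", "undefined")}.
#' @slot predicted character matrix of predicted labels (\code{NA} where
#'   undefined).
#' @seealso \code{\link{predictionGrid}}, \code{\link{meanPredictionScore}}
#' @exportClass PredictionGrid
setClass("PredictionGrid",
    representation(attribute = "character", thresholds = "numeric",
                   outcomes = "matrix", predicted = "matrix"))

setValidity("PredictionGrid", function(object) {
    msg <- character()
    oc <- object@outcomes
    if (!is.character(oc))
        msg <- c(msg, "'outcomes' must be a character matrix")
    else if (!all(oc %in% c("correct", "incorrect", "undefined")))
        msg <- c(msg, "outcomes must be correct/incorrect/undefined")
    if (ncol(object@outcomes) != length(object@thresholds))
        msg <- c(msg, "one outcome column per threshold is required")
    if (!identical(dim(object@outcomes), dim(object@predicted)))
        msg <- c(msg, "'predicted' must match 'outcomes' in shape")
    if (length(msg)) msg else TRUE
})
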