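#' Build a thresholded correlation network
#'
#' An edge joins two samples exactly when their correlation is greater than or
#' equal to \code{threshold} \emph{and} strictly positive. The strict
#' positivity clause makes threshold 0 reproduce the convention that the full
#' network contains all positive correlations and none of the negative ones;
#' negative correlations never form edges. All samples stay in the node set;
#' use \code{\link{isolatedNodes}} for the degree-zero ones.
#'
#' @param matrix a \code{\linkS4class{CorrelationMatrix}}.
#' @param threshold correlation threshold in [0, 1]. Comparison is an exact
#'   \code{>=} on stored values; thresholds are user-supplied round numbers.
#' @return a \code{\linkS4class{ThresholdedNetwork}}.
#' @examples
#' pt <- simulatePeakTable(nSamples = 12, nCompounds = 60, seed = 7)
#' net <- buildNetwork(correlationMatrix(pt), 0.5)
#' net
#' @export
buildNetwork <- function(matrix, threshold) {
    stopifnot(methods::is(matrix, "CorrelationMatrix"))
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        is.na(threshold) || threshold < 0 || threshold > 1)
        stop("'threshold' must be a single value in [0, 1]")
    v <- corValues(matrix)
    ids <- rownames(v)
    pr <- upperPairs(nrow(v))
    w <- v[pr]
    keep <- w >= threshold & w > 0
    edges <- data.frame(from = ids[pr[keep, "i"]],
                        to = ids[pr[keep, "j"]],
                        weight = w[keep],
                        stringsAsFactors = FALSE)
    methods::new("ThresholdedNetwork", threshold = threshold,
                 method = corMethod(matrix), nodes = ids, edges = edges)
}

#' Sweep a correlation matrix across a threshold grid
#'
#' Builds one network per threshold from the same matrix. Because the grids
#' are increasing, the edge sets are nested: every edge at a higher threshold
#' is present at every lower one.
#'
#' @param matrix a \code{\linkS4class{CorrelationMatrix}}.
#' @param thresholds strictly increasing values in [0, 1].
#' @return a list of \code{\linkS4class{ThresholdedNetwork}}, named by
#'   threshold.
#' @export
sweepNetworks <- function(matrix, thresholds) {
    checkThresholds(thresholds)
    nets <- lapply(thresholds, function(t) buildNetwork(matrix, t))
    names(nets) <- formatC(thresholds, format = "g")
    nets
}

checkThresholds <- function(thresholds) {
    if (!is.numeric(thresholds) || !length(thresholds) || anyNA(thresholds) ||
        any(thresholds < 0) || any(thresholds > 1))
        stop("'thresholds' must be values in [0, 1]")
    if (length(thresholds) > 1 && any(diff(thresholds) <= 0))
        stop("'thresholds' must be strictly increasing")
    invisible(thresholds)
}

#' @describeIn buildNetwork the network threshold.
#' @param x a ThresholdedNetwork
#' @export
setMethod("networkThreshold", "ThresholdedNetwork", function(x) x@threshold)

#' @describeIn buildNetwork all node ids (including isolated ones).
#' @export
setMethod("networkNodes", "ThresholdedNetwork", function(x) x@nodes)

#' @describeIn buildNetwork the edge table (from, to, weight).
#' @export
setMethod("networkEdges", "ThresholdedNetwork", function(x) x@edges)

#' @describeIn buildNetwork number of edges.
#' @export
setMethod("nEdges", "ThresholdedNetwork", function(x) nrow(x@edges))

#' @describeIn buildNetwork ids of degree-zero nodes.
#' @export
setMethod("isolatedNodes", "ThresholdedNetwork", function(x)
    setdiff(x@nodes, unique(c(x@edges$from, x@edges$to))))

#' @describeIn buildNetwork compact display.
#' @param object a ThresholdedNetwork
#' @export
setMethod("show", "ThresholdedNetwork", function(object) {
    cat(sprintf(
        "ThresholdedNetwork (%s, threshold %s): %d nodes, %d edges, %d isolated\n",
        object@method,
        if (is.na(object@threshold)) "ideal" else
            format(object@threshold), length(object@nodes),
        nrow(object@edges), length(isolatedNodes(object))))
})

# igraph view of the connected part of the network
asIgraph <- function(network) {
    igraph::graph_from_data_frame(
        network@edges[, c("from", "to", "weight")],
        directed = FALSE,
        vertices = data.frame(name = network@nodes))
}

#' Connected components of a thresholded network
#'
#' Standard undirected connectivity among the connected (degree >= 1) nodes;
#' isolated nodes are excluded. Components are returned largest first, ties
#' broken by the earliest member in node order; members are listed in node
#' order.
#'
#' @param x a \code{\linkS4class{ThresholdedNetwork}}.
#' @return a list of character vectors of sample ids.
#' @export
setMethod("connectedComponents", "ThresholdedNetwork", function(x) {
    if (!nrow(x@edges)) return(list())
    g <- asIgraph(x)
    memb <- igraph::components(g)$membership
    connected <- setdiff(x@nodes, isolatedNodes(x))
    memb <- memb[connected]
    comps <- split(names(memb), memb)
    comps <- lapply(comps, function(m) m[order(match(m, x@nodes))])
    sizes <- lengths(comps)
    first <- vapply(comps, function(m) match(m[1L], x@nodes), integer(1))
    unname(comps[order(-sizes, first, method = "radix")])
})

#' Size curve of a threshold sweep
#'
#' Per-threshold bookkeeping of how the network thins and fragments as the
#' threshold rises: edge count, number of connected (degree >= 1) nodes —
#' isolated nodes are dropped from this count, matching how sparse networks
#' are reported and drawn — and number of connected components among them.
#'
#' @param networks a non-empty list of
#'   \code{\linkS4class{ThresholdedNetwork}}, e.g. from
#'   \code{\link{sweepNetworks}}.
#' @return data.frame with columns \code{threshold}, \code{n_edges},
#'   \code{n_connected_nodes}, \code{n_components}.
#' @export
sizeCurve <- function(networks) {
    if (!length(networks)) stop("'networks' must be a non-empty list")
    rows <- lapply(networks, function(net) {
        stopifnot(methods::is(net, "ThresholdedNetwork"))
        data.frame(threshold = net@threshold,
                   n_edges = nrow(net@edges),
                   n_connected_nodes =
                       length(net@nodes) - length(isolatedNodes(net)),
                   n_components = length(connectedComponents(net)))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Export a network for Cytoscape
#'
#' Writes the edge set either as SIF lines (\code{source cc target}) or as an
#' edge-list CSV (\code{source, target, weight}); in both formats the source
#' precedes the target in node order. Isolated nodes do not appear in edge
#' files; pair the export with \code{\link{writeNodeAttributes}} to carry the
#' full node set and its attributes.
#'
#' @param network a \code{\linkS4class{ThresholdedNetwork}}.
#' @param path output file.
#' @param format \code{"sif"} or \code{"edge-csv"}.
#' @return invisibly, \code{path}.
#' @export
exportNetwork <- function(network, path, format = c("sif", "edge-csv")) {
    stopifnot(methods::is(network, "ThresholdedNetwork"))
    format <- match.arg(format)
    e <- network@edges
    if (format == "sif") {
        lines <- if (nrow(e)) paste(e$from, "cc", e$to) else character(0)
        writeLines(lines, path)
    } else {
        utils::write.csv(
            data.frame(source = e$from, target = e$to, weight = e$weight,
                       stringsAsFactors = FALSE),
            path, row.names = FALSE)
    }
    invisible(path)
}

#' Read an edge-list CSV back into an edge table
#'
#' Companion to \code{\link{exportNetwork}}'s \code{"edge-csv"} format; used
#' for round-trip checks and for feeding exported networks into other tools.
#'
#' @param path edge-list CSV with columns source, target, weight.
#' @return data.frame with columns \code{from}, \code{to}, \code{weight}.
#' @export
readEdgeCsv <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    data.frame(from = as.character(df$source), to = as.character(df$target),
               weight = as.numeric(df$weight), stringsAsFactors = FALSE)
}
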