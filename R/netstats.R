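# Resolve a labelling against a node set: named vectors may come in any
# order; unnamed vectors must match the node count and order.
resolveLabels <- function(labels, nodes) {
    if (!is.null(names(labels))) {
        miss <- setdiff(nodes, names(labels))
        if (length(miss))
            stop("missing label for node(s): ", paste(miss, collapse = ", "))
        labels <- labels[nodes]
    } else if (length(labels) != length(nodes)) {
        stop("'labels' must be named by node id or match the node count")
    }
    labels <- as.character(labels)
    if (anyNA(labels)) stop("labels must not contain NA")
    stats::setNames(labels, nodes)
}

#' Fraction of edges joining same-label nodes
#'
#' The edge similarity of a network under a categorical node attribute: the
#' number of edges whose two endpoints carry the same label, divided by the
#' number of edges. It is defined on an edge basis, never over clusters. With
#' no edges the quantity is undefined and \code{NA} is returned (never 0,
#' which would fake perfect dissimilarity).
#'
#' @param network a \code{\linkS4class{ThresholdedNetwork}}.
#' @param labels per-node category, named by sample id (or in node order).
#' @return similarity in [0, 1], or \code{NA} if the network has no edges.
#' @export
edgeSimilarity <- function(network, labels) {
    stopifnot(methods::is(network, "ThresholdedNetwork"))
    labels <- resolveLabels(labels, network@nodes)
    e <- network@edges
    if (!nrow(e)) return(NA_real_)
    mean(labels[e$from] == labels[e$to])
}

#' Edge-similarity curves across a threshold sweep
#'
#' Evaluates \code{\link{edgeSimilarity}} on the network built at each
#' threshold, for one or several labellings (typically the coarse sample-type
#' attribute and the finer origin attribute). Thresholds where the network has
#' no edges yield \code{NA} similarity.
#'
#' @param matrix a \code{\linkS4class{CorrelationMatrix}}.
#' @param labels a single labelling (named vector) or a named list of
#'   labellings, e.g. \code{list(sample_type = ..., origin = ...)}.
#' @param thresholds strictly increasing values in [0, 1].
#' @return data.frame with columns \code{threshold}, \code{attribute},
#'   \code{similarity}, \code{n_edges}.
#' @examples
#' pt <- simulatePeakTable(nSamples = 30, nCompounds = 200, seed = 2)
#' cm <- correlationMatrix(pt)
#' similarityCurves(cm, list(sample_type = sampleType(pt),
#'                           origin = origin(pt)), seq(0, 0.9, 0.1))
#' @export
similarityCurves <- function(matrix, labels, thresholds) {
    stopifnot(methods::is(matrix, "CorrelationMatrix"))
    checkThresholds(thresholds)
    if (!is.list(labels)) labels <- list(label = labels)
    if (is.null(names(labels)))
        names(labels) <- paste0("attribute", seq_along(labels))
    nets <- sweepNetworks(matrix, thresholds)
    out <- do.call(rbind, lapply(names(labels), function(attr) {
        sim <- vapply(nets, edgeSimilarity, numeric(1), labels = labels[[attr]])
        data.frame(threshold = thresholds, attribute = attr,
                   similarity = unname(sim),
                   n_edges = vapply(nets, nEdges, integer(1)),
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Weight-permutation null ensemble for edge similarity
#'
#' Control networks are produced by randomly permuting the multiset of
#' positive edge weights over the node pairs that carry positive weight in
#' the full (threshold-0) network, so each control network has exactly the
#' same correlation distribution as the original; each replicate is then
#' re-thresholded and its edge similarity computed. The ensemble mean and
#' standard deviation per threshold and attribute quantify how much observed
#' similarity exceeds what the weight distribution alone produces. Because a
#' weight-permuted network thresholded at \eqn{t} is a uniformly random
#' subset of the positive pairs, the expected null similarity at every
#' threshold equals the full-network similarity.
#'
#' Optionally (\code{scope = "all-pairs"}) the permutation can spread the
#' positive weights over all \eqn{n(n-1)/2} pairs (absent pairs receive no
#' weight), a sensitivity variant; the default matches the definition above.
#'
#' @param matrix a \code{\linkS4class{CorrelationMatrix}}.
#' @param labels labelling(s) as in \code{\link{similarityCurves}}.
#' @param thresholds strictly increasing values in [0, 1].
#' @param nReps ensemble size (>= 2); 100 is the conventional choice.
#' @param seed integer seed; one generator drives the whole ensemble, the
#'   replicate index advancing the stream, so a single seed reproduces it.
#' @param scope \code{"positive-pairs"} (default) or \code{"all-pairs"}.
#' @return data.frame with columns \code{threshold}, \code{attribute},
#'   \code{null_mean}, \code{null_sd}.
#' @export
nullEnsemble <- function(matrix, labels, thresholds, nReps = 100,
                         seed = NULL, scope = c("positive-pairs", "all-pairs")) {
    stopifnot(methods::is(matrix, "CorrelationMatrix"))
    checkThresholds(thresholds)
    scope <- match.arg(scope)
    if (!is.numeric(nReps) || length(nReps) != 1L || nReps < 2)
        stop("'nReps' must be an integer >= 2")
    if (!is.list(labels)) labels <- list(label = labels)
    if (is.null(names(labels)))
        names(labels) <- paste0("attribute", seq_along(labels))
    v <- corValues(matrix)
    ids <- rownames(v)
    pr <- upperPairs(nrow(v))
    w <- v[pr]
    pos <- w > 0
    if (!any(pos)) stop("no positive correlations; null ensemble undefined")
    same <- lapply(labels, function(lb) {
        lb <- resolveLabels(lb, ids)
        lb[pr[, "i"]] == lb[pr[, "j"]]
    })
    if (scope == "positive-pairs") {
        wPool <- w[pos]
        sameMat <- do.call(cbind, lapply(same, function(s) s[pos]))
    } else {
        wPool <- w
        sameMat <- do.call(cbind, same)
    }
    nPairs <- length(wPool)
    nT <- length(thresholds)
    nA <- length(labels)
    sims <- array(NA_real_, dim = c(nReps, nT, nA))
    withSeed(seed, {
        for (r in seq_len(nReps)) {
            wp <- wPool[sample.int(nPairs)]
            for (ti in seq_len(nT)) {
                keep <- wp >= thresholds[ti] & wp > 0
                if (any(keep))
                    for (ai in seq_len(nA))
                        sims[r, ti, ai] <- mean(sameMat[keep, ai])
            }
        }
    })
    out <- do.call(rbind, lapply(seq_len(nA), function(ai) {
        s <- matrix(sims[, , ai], nrow = nReps)
        data.frame(threshold = thresholds, attribute = names(labels)[ai],
                   null_mean = colMeans(s, na.rm = TRUE),
                   null_sd = apply(s, 2, stats::sd, na.rm = TRUE),
                   stringsAsFactors = FALSE)
    }))
    out$null_mean[is.nan(out$null_mean)] <- NA_real_
    rownames(out) <- NULL
    out
}

#' Attribute-defined ideal network
#'
#' The reference graph in which an edge is present exactly between pairs of
#' nodes sharing the attribute value: the network a perfect grouping by that
#' attribute would produce. Its edge count is \eqn{\sum_c n_c (n_c - 1) / 2}
#' over label classes.
#'
#' @param labels per-node category, named by sample id.
#' @return a \code{\linkS4class{ThresholdedNetwork}} with method
#'   \code{"ideal"}, threshold \code{NA}, and unit edge weights.
#' @export
idealNetwork <- function(labels) {
    if (is.null(names(labels)))
        names(labels) <- sprintf("S%03d", seq_along(labels))
    nodes <- names(labels)
    labels <- resolveLabels(labels, nodes)
    pr <- upperPairs(length(nodes))
    keep <- labels[pr[, "i"]] == labels[pr[, "j"]]
    edges <- data.frame(from = nodes[pr[keep, "i"]],
                        to = nodes[pr[keep, "j"]],
                        weight = rep.int(1, sum(keep)),
                        stringsAsFactors = FALSE)
    methods::new("ThresholdedNetwork", threshold = NA_real_,
                 method = "ideal", nodes = nodes, edges = edges)
}

#' Link accuracy against the ideal network, across thresholds
#'
#' Compares the thresholded network's links with the attribute's ideal
#' network over all \eqn{n(n-1)/2} node pairs: a pair is a true positive when
#' linked in both, a true negative when linked in neither, a false positive
#' when linked only in the thresholded network, and a false negative when
#' linked only in the ideal one. The accuracy
#' \eqn{\alpha = (TP + TN) / \binom{n}{2}} measures how closely the network at
#' that threshold matches the grouping the attribute would ideally induce.
#'
#' @param matrix a \code{\linkS4class{CorrelationMatrix}}.
#' @param labels per-node category, named by sample id.
#' @param thresholds strictly increasing values in [0, 1].
#' @param attribute name recorded in the output's \code{attribute} column.
#' @return data.frame with columns \code{threshold}, \code{attribute},
#'   \code{tp}, \code{tn}, \code{fp}, \code{fn}, \code{accuracy}.
#' @export
accuracyCurve <- function(matrix, labels, thresholds, attribute = "label") {
    stopifnot(methods::is(matrix, "CorrelationMatrix"))
    checkThresholds(thresholds)
    v <- corValues(matrix)
    labels <- resolveLabels(labels, rownames(v))
    pr <- upperPairs(nrow(v))
    w <- v[pr]
    same <- labels[pr[, "i"]] == labels[pr[, "j"]]
    total <- length(w)
    rows <- lapply(thresholds, function(t) {
        present <- w >= t & w > 0
        tp <- sum(present & same)
        fp <- sum(present & !same)
        fn <- sum(!present & same)
        tn <- sum(!present & !same)
        data.frame(threshold = t, attribute = attribute,
                   tp = tp, tn = tn, fp = fp, fn = fn,
                   accuracy = (tp + tn) / total,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
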