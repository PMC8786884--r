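# Adjacency (logical) and weight matrices of a network, in node order.
adjacencyMatrices <- function(network) {
    n <- length(network@nodes)
    A <- matrix(FALSE, n, n, dimnames = list(network@nodes, network@nodes))
    W <- matrix(0, n, n, dimnames = dimnames(A))
    e <- network@edges
    if (nrow(e)) {
        i <- match(e$from, network@nodes)
        j <- match(e$to, network@nodes)
        A[cbind(i, j)] <- TRUE
        A[cbind(j, i)] <- TRUE
        W[cbind(i, j)] <- e$weight
        W[cbind(j, i)] <- e$weight
    }
    list(A = A, W = W)
}

# Voter matrix at the given radius: V[u, v] = TRUE when v votes for u.
voterMatrix <- function(A, radius) {
    if (radius == 1) return(A)
    A2 <- A | ((A %*% A) > 0)
    diag(A2) <- FALSE
    A2
}

#' Majority-vote label inference for one node
#'
#' Predicts a node's attribute as the most frequent label among its network
#' neighbours; with \code{radius = 2} the voters are all nodes at graph
#' distance 1 or 2 (each counted once, unweighted), a way to enhance the vote
#' statistics when few labelled neighbours are available. The queried node's
#' own label is never consulted. With zero voters, or a tie for the top count,
#' the prediction is undefined and \code{NA} is returned. Setting
#' \code{weighted = TRUE} weights each distance-1 vote by its edge
#' correlation (distance-2 voters by the best two-edge path product), a
#' tie-reducing variant that is off by default.
#'
#' @param network a \code{\linkS4class{ThresholdedNetwork}}.
#' @param labels per-node category, named by sample id; the queried node's
#'   entry may be absent.
#' @param node the sample id to predict.
#' @param radius 1 (nearest neighbours) or 2 (next-to-nearest included).
#' @param weighted logical; weight votes by edge correlation.
#' @return the predicted label, or \code{NA} when undefined.
#' @export
majorityVote <- function(network, labels, node, radius = 1,
                         weighted = FALSE) {
    stopifnot(methods::is(network, "ThresholdedNetwork"))
    if (!node %in% network@nodes) stop("unknown node: ", node)
    if (!radius %in% c(1, 2)) stop("'radius' must be 1 or 2")
    if (is.null(names(labels)))
        stop("'labels' must be named by sample id")
    labels <- stats::setNames(as.character(labels), names(labels))
    am <- adjacencyMatrices(network)
    V <- voterMatrix(am$A, radius)
    voters <- network@nodes[V[node, ]]
    voters <- voters[voters %in% names(labels)]
    if (!length(voters)) return(NA_character_)
    if (!weighted) {
        counts <- table(labels[voters])
    } else {
        wts <- voteWeights(am, node, voters, radius)
        counts <- tapply(wts, labels[voters], sum)
    }
    top <- max(counts)
    winners <- names(counts)[counts == top]
    if (length(winners) != 1L) return(NA_character_)
    winners
}

# Edge-correlation vote weights: direct neighbours use their edge weight,
# distance-2 voters the best min over any connecting two-edge path.
voteWeights <- function(am, node, voters, radius) {
    direct <- am$W[node, voters]
    if (radius == 1) return(direct)
    need <- direct == 0
    if (any(need)) {
        Wn <- am$W[node, ]
        for (v in voters[need]) {
            path <- pmin(Wn, am$W[v, ])
            direct[v == voters] <- max(path)
        }
    }
    direct
}

#' Leave-one-out majority-vote grid over a threshold sweep
#'
#' For every node and every threshold, builds the network, hides the node's
#' own label, and predicts it by \code{\link{majorityVote}} from its
#' neighbours' labels; the true label is used only to score the prediction.
#' Cells are \code{"correct"}, \code{"incorrect"}, or \code{"undefined"}
#' (no voters, or a tied vote) — the latter are the blank cells of a
#' prediction heatmap, since sparse high-threshold networks cannot supply
#' votes for every node.
#'
#' @param matrix a \code{\linkS4class{CorrelationMatrix}}.
#' @param labels per-node category, named by sample id.
#' @param thresholds strictly increasing values in [0, 1].
#' @param attribute name recorded on the grid (\code{"sampleType"},
#'   \code{"origin"}, or any descriptive string).
#' @param radius voting radius, 1 or 2.
#' @param weighted logical; weight votes by edge correlation.
#' @return a \code{\linkS4class{PredictionGrid}}.
#' @examples
#' pt <- simulatePeakTable(nSamples = 20, nCompounds = 100, seed = 3)
#' cm <- correlationMatrix(pt)
#' g <- predictionGrid(cm, sampleType(pt), seq(0.1, 0.7, 0.2), "sampleType")
#' meanPredictionScore(g)
#' @export
predictionGrid <- function(matrix, labels, thresholds,
                           attribute = "label", radius = 1,
                           weighted = FALSE) {
    stopifnot(methods::is(matrix, "CorrelationMatrix"))
    checkThresholds(thresholds)
    if (!radius %in% c(1, 2)) stop("'radius' must be 1 or 2")
    ids <- sampleIds(matrix)
    labels <- resolveLabels(labels, ids)
    n <- length(ids)
    classes <- sort(unique(labels))
    ind <- outer(labels, classes, "==") * 1     # n x k membership indicator
    outcomes <- matrix("undefined", n, length(thresholds),
                       dimnames = list(ids, formatC(thresholds, format = "g")))
    predicted <- matrix(NA_character_, n, length(thresholds),
                        dimnames = dimnames(outcomes))
    for (ti in seq_along(thresholds)) {
        net <- buildNetwork(matrix, thresholds[ti])
        am <- adjacencyMatrices(net)
        V <- voterMatrix(am$A, radius)
        votes <- if (!weighted) {
            (V * 1) %*% ind
        } else {
            voteWeightMatrix(am, V, radius) %*% ind
        }
        nVoters <- rowSums(V)
        top <- apply(votes, 1L, max)
        nTop <- rowSums(votes == top)
        defined <- nVoters > 0 & nTop == 1L
        pred <- classes[max.col(votes, ties.method = "first")]
        predicted[defined, ti] <- pred[defined]
        outcomes[defined, ti] <-
            ifelse(pred[defined] == labels[defined], "correct", "incorrect")
    }
    methods::new("PredictionGrid", attribute = attribute,
                 thresholds = as.numeric(thresholds),
                 outcomes = outcomes, predicted = predicted)
}

# Vote-weight matrix matching voterMatrix: direct edges keep their weight,
# distance-2-only voters the best min over two-edge paths.
voteWeightMatrix <- function(am, V, radius) {
    Wv <- am$W
    if (radius == 2) {
        extra <- V & am$W == 0
        if (any(extra)) {
            idx <- which(extra, arr.ind = TRUE)
            for (r in seq_len(nrow(idx))) {
                u <- idx[r, 1L]; v <- idx[r, 2L]
                Wv[u, v] <- max(pmin(am$W[u, ], am$W[v, ]))
            }
        }
    }
    Wv * V
}

#' @describeIn predictionGrid the outcome matrix (nodes x thresholds).
#' @param x a PredictionGrid
#' @export
setMethod("voteOutcomes", "PredictionGrid", function(x) x@outcomes)

#' @describeIn predictionGrid the threshold grid.
#' @export
setMethod("voteThresholds", "PredictionGrid", function(x) x@thresholds)

#' @describeIn predictionGrid compact display.
#' @param object a PredictionGrid
#' @export
setMethod("show", "PredictionGrid", function(object) {
    cat(sprintf("PredictionGrid (%s): %d nodes x %d thresholds\n",
                object@attribute, nrow(object@outcomes),
                ncol(object@outcomes)))
    tab <- table(factor(object@outcomes,
                        c("correct", "incorrect", "undefined")))
    cat(sprintf("  correct %d | incorrect %d | undefined %d\n",
                tab[1L], tab[2L], tab[3L]))
})

#' Mean prediction score per threshold
#'
#' The fraction of correct predictions among the defined (non-blank) cells at
#' each threshold. Thresholds where no node has a defined outcome yield
#' \code{NA}.
#'
#' @param grid a \code{\linkS4class{PredictionGrid}}.
#' @return data.frame with columns \code{threshold}, \code{score},
#'   \code{n_correct}, \code{n_incorrect}, \code{n_undefined}.
#' @export
meanPredictionScore <- function(grid) {
    stopifnot(methods::is(grid, "PredictionGrid"))
    oc <- grid@outcomes
    nC <- colSums(oc == "correct")
    nI <- colSums(oc == "incorrect")
    nU <- colSums(oc == "undefined")
    score <- ifelse(nC + nI > 0, nC / (nC + nI), NA_real_)
    data.frame(threshold = grid@thresholds, score = score,
               n_correct = as.integer(nC), n_incorrect = as.integer(nI),
               n_undefined = as.integer(nU), row.names = NULL)
}
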