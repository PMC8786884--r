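# Independent oracles and small fixtures used across the suite.

# Pearson correlation written out from its definition; independent of
# stats::cor.
bfPearson <- function(x, y) {
    dx <- x - mean(x)
    dy <- y - mean(y)
    sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Spearman as Pearson on midranks (base rank() uses average ranks for ties).
bfSpearman <- function(x, y) bfPearson(rank(x), rank(y))

# Connected components by brute-force transitive closure of the adjacency
# matrix (boolean matrix powers until fixpoint).
closureComponents <- function(nodes, edgeFrom, edgeTo) {
    n <- length(nodes)
    A <- diag(n) > 0
    i <- match(edgeFrom, nodes)
    j <- match(edgeTo, nodes)
    A[cbind(i, j)] <- TRUE
    A[cbind(j, i)] <- TRUE
    repeat {
        A2 <- (A %*% A) > 0
        if (identical(A2, A)) break
        A <- A2
    }
    connected <- nodes[rowSums(A) > 1]
    comps <- unique(apply(A[match(connected, nodes), , drop = FALSE], 1,
                          function(r) paste(sort(nodes[r]), collapse = "|")))
    lapply(strsplit(comps, "|", fixed = TRUE), sort)
}

# A tiny PeakTable from a samples-in-rows matrix.
miniTable <- function(m, stage = NULL, orig = NULL) {
    n <- nrow(m)
    if (is.null(stage)) stage <- rep("fermented", n)
    if (is.null(orig)) orig <- rep("Ghana", n)
    if (is.null(rownames(m))) rownames(m) <- sprintf("S%03d", seq_len(n))
    PeakTable(m, sampleType = stage, origin = orig)
}

# A CorrelationMatrix with prescribed off-diagonal entries (upper triangle,
# column-major order), for constructing exact toy networks.
toyCorrMatrix <- function(offdiag, n, ids = sprintf("S%03d", seq_len(n)),
                          method = "spearman") {
    v <- diag(n)
    v[upper.tri(v)] <- offdiag
    v <- v + t(v) - diag(n)
    dimnames(v) <- list(ids, ids)
    methods::new("CorrelationMatrix", values = v, method = method)
}

# Brute-force TP/TN/FP/FN of a thresholded matrix against the same-label
# ideal network, by explicit enumeration of every pair.
bfAccuracy <- function(values, labels, threshold) {
    n <- nrow(values)
    tp <- tn <- fp <- fn <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        present <- values[i, j] >= threshold && values[i, j] > 0
        ideal <- labels[i] == labels[j]
        if (present && ideal) tp <- tp + 1
        else if (present && !ideal) fp <- fp + 1
        else if (!present && ideal) fn <- fn + 1
        else tn <- tn + 1
    }
    c(tp = tp, tn = tn, fp = fp, fn = fn)
}
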