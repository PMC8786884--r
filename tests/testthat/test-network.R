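test_that("edge rule keeps correlations >= threshold and > 0 only", {
    cm <- toyCorrMatrix(c(0.9, 0.2, -0.1), n = 3,
                        ids = c("s1", "s2", "s3"))
    net <- buildNetwork(cm, 0.5)
    e <- networkEdges(net)
    expect_equal(nrow(e), 1L)
    expect_identical(c(e$from, e$to), c("s1", "s2"))
    expect_equal(e$weight, 0.9)
    expect_identical(isolatedNodes(net), "s3")

    # negative correlations never form edges, even at threshold 0
    net0 <- buildNetwork(cm, 0)
    expect_equal(nEdges(net0), 2L)   # the two positive pairs

    # threshold 1 with all off-diagonals < 1: empty graph, all isolated
    net1 <- buildNetwork(cm, 1)
    expect_equal(nEdges(net1), 0L)
    expect_identical(isolatedNodes(net1), c("s1", "s2", "s3"))

    expect_error(buildNetwork(cm, 1.2), "threshold")
    expect_error(buildNetwork(cm, -0.1), "threshold")
})

test_that("an all-positive matrix at threshold 0 gives the complete graph", {
    set.seed(7)
    pt <- simulatePeakTable(nSamples = 9, nCompounds = 30, seed = 7)
    cm <- correlationMatrix(pt)
    v <- corValues(cm)
    nPos <- sum(v[upper.tri(v)] > 0)
    expect_equal(nEdges(buildNetwork(cm, 0)), nPos)
    if (nPos == choose(9, 2))
        expect_length(isolatedNodes(buildNetwork(cm, 0)), 0)
})

test_that("edge sets are nested along an increasing threshold sweep", {
    pt <- simulatePeakTable(nSamples = 12, nCompounds = 60, seed = 13)
    cm <- correlationMatrix(pt)
    nets <- sweepNetworks(cm, seq(0.1, 0.9, 0.1))
    counts <- vapply(nets, nEdges, integer(1))
    expect_true(all(diff(counts) <= 0))
    key <- function(net) paste(networkEdges(net)$from,
                               networkEdges(net)$to)
    for (k in seq_len(length(nets) - 1))
        expect_true(all(key(nets[[k + 1]]) %in% key(nets[[k]])))

    expect_error(sweepNetworks(cm, c(0.5, 0.3)), "increasing")
    expect_error(sweepNetworks(cm, c(0.1, 0.1)), "increasing")
})

test_that("a uniform matrix steps from complete to empty across its value", {
    cm <- toyCorrMatrix(rep(0.55, 6), n = 4)
    nets <- sweepNetworks(cm, c(0.5, 0.6))
    expect_equal(nEdges(nets[[1]]), 6L)
    expect_equal(nEdges(nets[[2]]), 0L)
})

test_that("size curve counts edges, connected nodes and components", {
    empty <- buildNetwork(toyCorrMatrix(c(-0.5, -0.5, -0.5), 3), 0.5)
    sc <- sizeCurve(list(empty))
    expect_equal(as.numeric(sc[1, -1]), c(0, 0, 0))

    single <- buildNetwork(toyCorrMatrix(c(0.8, 0.1, 0.1), 3), 0.5)
    sc <- sizeCurve(list(single))
    expect_equal(as.numeric(sc[1, -1]), c(1, 2, 1))

    # 5 nodes, two disjoint edges: (1,2) and (3,4), node 5 isolated
    m <- diag(5); m[1, 2] <- m[2, 1] <- 0.9; m[3, 4] <- m[4, 3] <- 0.8
    ids <- sprintf("S%03d", 1:5); dimnames(m) <- list(ids, ids)
    cm <- methods::new("CorrelationMatrix", values = m, method = "spearman")
    sc <- sizeCurve(list(buildNetwork(cm, 0.5)))
    expect_equal(sc$n_components, 2L)
    expect_equal(sc$n_connected_nodes, 4L)
})

test_that("components agree with a transitive-closure oracle on random graphs", {
    set.seed(21)
    for (rep in 1:10) {
        n <- 20
        v <- diag(n)
        ut <- upper.tri(v)
        vals <- ifelse(runif(sum(ut)) < 0.08, runif(sum(ut), 0.6, 1), 0)
        v[ut] <- vals; v <- v + t(v) - diag(n)
        ids <- sprintf("N%02d", 1:n); dimnames(v) <- list(ids, ids)
        cm <- methods::new("CorrelationMatrix", values = v,
                           method = "spearman")
        net <- buildNetwork(cm, 0.5)
        got <- connectedComponents(net)
        e <- networkEdges(net)
        want <- closureComponents(ids, e$from, e$to)
        expect_setequal(vapply(got, function(m) paste(sort(m), collapse = "|"),
                               character(1)),
                        vapply(want, function(m) paste(m, collapse = "|"),
                               character(1)))
        # components come out largest first
        expect_true(all(diff(lengths(got)) <= 0))
        # each component is internally connected and maximal by construction
        # of the oracle comparison above
    }
})

test_that("component member lists follow node order and path graphs cohere", {
    cm <- toyCorrMatrix(c(0.9, 0, 0.9, 0, 0, 0), n = 4,
                        ids = c("a", "b", "c", "d"))
    # edges a-b, b-c: one component {a,b,c}; d isolated
    comps <- connectedComponents(buildNetwork(cm, 0.5))
    expect_length(comps, 1)
    expect_identical(comps[[1]], c("a", "b", "c"))
})

test_that("network export round-trips (edge-csv) and emits SIF lines", {
    pt <- simulatePeakTable(nSamples = 8, nCompounds = 30, seed = 5)
    net <- buildNetwork(correlationMatrix(pt), 0.5)
    f <- withr::local_tempfile(fileext = ".csv")
    exportNetwork(net, f, format = "edge-csv")
    back <- readEdgeCsv(f)
    expect_identical(back$from, networkEdges(net)$from)
    expect_identical(back$to, networkEdges(net)$to)
    expect_equal(back$weight, networkEdges(net)$weight, tolerance = 1e-12)

    single <- buildNetwork(toyCorrMatrix(c(0.8, 0.1, 0.1), 3), 0.5)
    sf <- withr::local_tempfile(fileext = ".sif")
    exportNetwork(single, sf, format = "sif")
    expect_identical(readLines(sf), "S001 cc S002")

    emptyNet <- buildNetwork(toyCorrMatrix(c(-1, -1, -1) * 0.2, 3), 0.5)
    exportNetwork(emptyNet, sf, format = "sif")
    expect_identical(readLines(sf), character(0))
})
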