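test_that("majority vote follows the strict neighbour majority", {
    # star: q connected to three labelled neighbours F, F, U
    ids <- c("q", "n1", "n2", "n3")
    # pairs (q,n1) (q,n2) (n1,n2) (q,n3) (n1,n3) (n2,n3)
    off <- c(0.9, 0.8, 0.1, 0.7, 0.1, 0.1)
    cm <- toyCorrMatrix(off, 4, ids = ids)
    net <- buildNetwork(cm, 0.5)
    labels <- setNames(c("F", "F", "U"), c("n1", "n2", "n3"))
    expect_identical(majorityVote(net, labels, "q"), "F")

    # isolated node: undefined
    iso <- buildNetwork(toyCorrMatrix(c(0.9, 0.1, 0.1), 3,
                                      ids = c("a", "b", "c")), 0.5)
    expect_true(is.na(majorityVote(iso, setNames(c("F", "U"), c("a", "b")),
                                   "c")))
    expect_error(majorityVote(net, labels, "nope"), "unknown node")
})

test_that("radius-2 voting reaches next-to-nearest neighbours, once each,
           and ties are undefined", {
    # path u - v - w
    ids <- c("u", "v", "w")
    off <- c(0.9, 0, 0.9)   # (u,v) (u,w) (v,w)
    cm <- toyCorrMatrix(off, 3, ids = ids)
    net <- buildNetwork(cm, 0.5)
    labels <- setNames(c("F", "U"), c("v", "w"))
    # radius 1: only v votes
    expect_identical(majorityVote(net, labels, "u", radius = 1), "F")
    # radius 2: v and w vote once each -> tie -> undefined
    expect_true(is.na(majorityVote(net, labels, "u", radius = 2)))
})

test_that("correlation-weighted voting can break ties", {
    ids <- c("q", "a", "b")
    off <- c(0.9, 0.6, 0.1)   # (q,a)=0.9 (q,b)=0.6 (a,b)=0.1
    cm <- toyCorrMatrix(off, 3, ids = ids)
    net <- buildNetwork(cm, 0.5)
    labels <- setNames(c("F", "U"), c("a", "b"))
    expect_true(is.na(majorityVote(net, labels, "q")))  # 1 vs 1 unweighted
    expect_identical(majorityVote(net, labels, "q", weighted = TRUE), "F")
})

test_that("the queried node's own label never influences its prediction", {
    pt <- simulatePeakTable(nSamples = 15, nCompounds = 80, seed = 17)
    cm <- correlationMatrix(pt)
    net <- buildNetwork(cm, 0.4)
    labels <- sampleType(pt)
    for (node in sampleIds(pt)[c(1, 7, 12)]) {
        flipped <- labels
        flipped[node] <- "something-else"
        expect_identical(majorityVote(net, labels, node),
                         majorityVote(net, flipped, node))
    }
})

test_that("prediction grids score homogeneous neighbourhoods correct and
           empty networks undefined", {
    # two same-label cliques, no cross edges above 0: every connected node
    # is voted by its own class only
    ids <- paste0("s", 1:6)
    v <- diag(6)
    v[1:3, 1:3] <- 0.9; v[4:6, 4:6] <- 0.8; diag(v) <- 1
    dimnames(v) <- list(ids, ids)
    cm <- methods::new("CorrelationMatrix", values = v, method = "spearman")
    labels <- setNames(rep(c("A", "B"), each = 3), ids)
    g <- predictionGrid(cm, labels, c(0.5, 0.95), attribute = "sampleType")
    oc <- voteOutcomes(g)
    expect_true(all(oc[, 1] == "correct"))
    # above the maximum correlation the whole column is undefined
    expect_true(all(oc[, 2] == "undefined"))

    counts <- table(factor(oc, c("correct", "incorrect", "undefined")))
    expect_equal(sum(counts), length(ids) * 2)
})

test_that("grid outcome counts always partition the node set", {
    pt <- simulatePeakTable(nSamples = 12, nCompounds = 50, seed = 23)
    cm <- correlationMatrix(pt)
    th <- seq(0.1, 0.9, 0.2)
    for (radius in c(1, 2)) {
        g <- predictionGrid(cm, origin(pt), th, "origin", radius = radius)
        oc <- voteOutcomes(g)
        perThreshold <- colSums(oc == "correct") +
            colSums(oc == "incorrect") + colSums(oc == "undefined")
        expect_equal(unname(perThreshold), rep(12L, length(th)))
    }
})

test_that("mean prediction score averages over defined cells only", {
    oc <- matrix(c("correct", "correct", "correct", "incorrect", "undefined",
                   rep("undefined", 5),
                   rep("correct", 5)),
                 nrow = 5,
                 dimnames = list(paste0("s", 1:5), c("a", "b", "c")))
    pred <- matrix(NA_character_, 5, 3, dimnames = dimnames(oc))
    g <- methods::new("PredictionGrid", attribute = "origin",
                      thresholds = c(0.1, 0.5, 0.9),
                      outcomes = oc, predicted = pred)
    sc <- meanPredictionScore(g)
    expect_equal(sc$score, c(0.75, NA, 1))
    expect_equal(sc$n_undefined, c(1L, 5L, 0L))
})

test_that("with unanimous neighbourhood labels, radius-2 votes are correct
           for every connected node", {
    ids <- paste0("s", 1:6)
    v <- diag(6)
    v[1:3, 1:3] <- 0.9; v[4:6, 4:6] <- 0.8; diag(v) <- 1
    dimnames(v) <- list(ids, ids)
    cm <- methods::new("CorrelationMatrix", values = v, method = "spearman")
    labels <- setNames(rep(c("A", "B"), each = 3), ids)
    g <- predictionGrid(cm, labels, 0.5, "sampleType", radius = 2)
    expect_true(all(voteOutcomes(g) == "correct"))
})
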