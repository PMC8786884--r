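# 4-node toy used repeatedly: labels A,A,B,B; positive pairs chosen so that
# at threshold 0.5 the edges are exactly (A1,A2), (A1,B1), (B1,B2), (A2,B2).
toy4 <- function() {
    ids <- c("A1", "A2", "B1", "B2")
    # upper triangle order: (A1,A2) (A1,B1) (A2,B1) (A1,B2) (A2,B2) (B1,B2)
    off <- c(0.9, 0.8, 0.1, 0.1, 0.7, 0.6)
    list(cm = toyCorrMatrix(off, 4, ids = ids),
         labels = setNames(c("A", "A", "B", "B"), ids))
}

test_that("edge similarity is the same-label edge fraction", {
    t4 <- toy4()
    net <- buildNetwork(t4$cm, 0.5)
    expect_equal(nEdges(net), 4L)
    expect_equal(edgeSimilarity(net, t4$labels), 0.5)  # 2 of 4 same-label

    oneLab <- setNames(rep("X", 4), sampleIds(t4$cm))
    expect_equal(edgeSimilarity(net, oneLab), 1)

    emptyNet <- buildNetwork(t4$cm, 0.95)
    expect_true(is.na(edgeSimilarity(emptyNet, t4$labels)))

    expect_error(edgeSimilarity(net, t4$labels[-1]), "missing label")
})

test_that("similarity curves match hand counts on the toy matrix", {
    t4 <- toy4()
    curves <- similarityCurves(t4$cm, list(lab = t4$labels),
                               c(0.5, 0.65, 0.75, 0.85, 0.95))
    # t=0.5: edges .9 .8 .7 .6 -> same-label .9 .6 -> 2/4
    # t=0.65: edges .9 .8 .7 -> same-label .9 -> 1/3
    # t=0.75: edges .9 .8 -> 1/2; t=0.85: edge .9 -> 1/1; t=0.95: none
    expect_equal(curves$similarity, c(2/4, 1/3, 1/2, 1, NA))
    expect_equal(curves$n_edges, c(4L, 3L, 2L, 1L, 0L))
})

test_that("ideal networks link exactly the same-label pairs", {
    net <- idealNetwork(setNames(c("A", "A", "B"), c("x", "y", "z")))
    e <- networkEdges(net)
    expect_equal(nrow(e), 1L)
    expect_identical(c(e$from, e$to), c("x", "y"))

    expect_equal(nEdges(idealNetwork(setNames(letters[1:4], LETTERS[1:4]))),
                 0L)

    # class sizes (3, 2): choose(3,2) + choose(2,2) = 3 + 1 = 4 edges
    labs <- setNames(c("p", "p", "p", "q", "q"), paste0("n", 1:5))
    expect_equal(nEdges(idealNetwork(labs)), 4L)
})

test_that("accuracy classifies all pairs and matches the worked example", {
    ids <- c("A1", "A2", "B1", "B2")
    labels <- setNames(c("A", "A", "B", "B"), ids)
    # network edges at 0.5: (A1,A2) and (A1,B1) only
    off <- c(0.9, 0.8, 0.1, 0.1, 0.2, 0.3)
    cm <- toyCorrMatrix(off, 4, ids = ids)
    acc <- accuracyCurve(cm, labels, 0.5)
    expect_equal(acc$tp, 1L)
    expect_equal(acc$fp, 1L)
    expect_equal(acc$fn, 1L)
    expect_equal(acc$tn, 3L)
    expect_equal(acc$accuracy, 4 / 6)
})

test_that("a network identical to the ideal one has accuracy 1, an empty
           one scores the cross-label pair fraction", {
    ids <- c("A1", "A2", "B1", "B2")
    labels <- setNames(c("A", "A", "B", "B"), ids)
    # same-label pairs get 0.9, cross-label pairs get 0.1 -> at 0.5 the
    # thresholded network equals the ideal network
    off <- c(0.9, 0.1, 0.1, 0.1, 0.1, 0.9)
    cm <- toyCorrMatrix(off, 4, ids = ids)
    expect_equal(accuracyCurve(cm, labels, 0.5)$accuracy, 1)

    # empty network: TN = cross-label pairs = 4 of 6
    expect_equal(accuracyCurve(cm, labels, 0.95)$accuracy, 4 / 6)
})

test_that("TP/TN/FP/FN conserve the pair count and match brute force", {
    set.seed(31)
    for (rep in 1:25) {
        n <- sample(3:8, 1)
        ids <- paste0("s", seq_len(n))
        nOff <- choose(n, 2)
        off <- round(runif(nOff, -0.5, 1), 2)
        cm <- toyCorrMatrix(off, n, ids = ids)
        labels <- setNames(sample(c("u", "f", "l"), n, replace = TRUE), ids)
        t <- sample(c(0, 0.3, 0.5, 0.8), 1)
        acc <- accuracyCurve(cm, labels, if (t == 0) t else c(0, t))
        last <- acc[nrow(acc), ]
        expect_equal(last$tp + last$tn + last$fp + last$fn, nOff)
        bf <- bfAccuracy(corValues(cm), labels[ids], t)
        expect_equal(c(tp = last$tp, tn = last$tn, fp = last$fp,
                       fn = last$fn), bf)
        expect_equal(last$accuracy, (bf["tp"] + bf["tn"]) / nOff,
                     ignore_attr = TRUE)
    }
})

test_that("null ensembles are deterministic under a seed and forced to 1
           when all labels agree", {
    t4 <- toy4()
    oneLab <- setNames(rep("X", 4), sampleIds(t4$cm))
    nul <- nullEnsemble(t4$cm, oneLab, c(0.5, 0.7), nReps = 50, seed = 1)
    expect_equal(nul$null_mean, c(1, 1))
    expect_equal(nul$null_sd, c(0, 0))

    a <- nullEnsemble(t4$cm, t4$labels, c(0.3, 0.6), nReps = 100, seed = 9)
    b <- nullEnsemble(t4$cm, t4$labels, c(0.3, 0.6), nReps = 100, seed = 9)
    expect_identical(a, b)
    c2 <- nullEnsemble(t4$cm, t4$labels, c(0.3, 0.6), nReps = 100, seed = 10)
    expect_false(identical(a, c2))
})

test_that("expected null similarity at any threshold is the full-network
           similarity", {
    # 6-node toy with two label classes and a spread of positive weights
    ids <- paste0("s", 1:6)
    set.seed(5)
    off <- runif(choose(6, 2), -0.2, 0.95)
    cm <- toyCorrMatrix(round(off, 2), 6, ids = ids)
    labels <- setNames(c("A", "A", "A", "B", "B", "B"), ids)
    s0 <- edgeSimilarity(buildNetwork(cm, 0), labels)
    nul <- nullEnsemble(cm, labels, c(0, 0.4, 0.7), nReps = 2000, seed = 3)
    for (k in seq_len(nrow(nul))) {
        se <- nul$null_sd[k] / sqrt(2000)
        expect_lt(abs(nul$null_mean[k] - s0), max(3 * se, 1e-12))
    }
})

test_that("the all-pairs permutation scope dilutes high-threshold networks
           but keeps the similarity expectation", {
    t4 <- toy4()
    nul <- nullEnsemble(t4$cm, t4$labels, c(0, 0.5), nReps = 500, seed = 2,
                        scope = "all-pairs")
    s0 <- edgeSimilarity(buildNetwork(t4$cm, 0), t4$labels)
    expect_lt(abs(nul$null_mean[1] - s0), 3 * nul$null_sd[1] / sqrt(500) + 1e-12)
})
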