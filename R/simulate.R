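#' Simulate an LC-MS-like peak table with nested group structure
#'
#' Generates a synthetic peak-area table carrying the two-level structure the
#' correlation-network analysis assumes: a strong coarse effect (processing
#' stage) and a weaker fine effect (origin) nested within it, plus per-sample
#' noise. Profiles are exponentiated Gaussians: for sample \eqn{\alpha} in
#' stage \eqn{s} and origin \eqn{o}, the latent log profile is
#' \deqn{x_\alpha = b + a\,u_s + c\,w_{s,o} + \sigma\,\varepsilon_\alpha,}
#' where \eqn{b} (shared baseline), the per-stage vectors \eqn{u_s}, the
#' per-(stage, origin) vectors \eqn{w_{s,o}} and the per-sample noise
#' \eqn{\varepsilon_\alpha} are independent standard Gaussian vectors over
#' compounds, drawn once per table. Peak areas are \eqn{\exp(x_\alpha)},
#' giving nonnegative, heavy-tailed intensities; because \eqn{\exp} is
#' strictly increasing, Spearman correlations between samples equal those of
#' the latent Gaussian layer, where the expected correlation between two
#' samples is
#' \deqn{(\sigma_b^2 + a^2 [\mathrm{same\ stage}] + c^2 [\mathrm{same\ origin}])
#'   / (\sigma_b^2 + a^2 + c^2 + \sigma^2).}
#' Same-stage correlations therefore exceed cross-stage ones in expectation,
#' and same-origin (within stage) exceed cross-origin ones, whenever the
#' corresponding effect scale is positive.
#'
#' Samples are allocated to stage-by-origin cells deterministically by largest
#' remainder on the product weights, so the inventory is a pure function of
#' the configuration. The returned table is normalized to per-sample sum 100
#' and its compounds are sorted by descending mean peak area, the layout the
#' reader/writer functions use.
#'
#' @param nSamples number of samples (>= 2); default 140.
#' @param stageLabels processing-stage category names.
#' @param originLabels origin category names.
#' @param originProportions nonnegative allocation weights per origin (sum
#'   > 0); the default makes the largest origin about four times the smallest.
#' @param stageProportions nonnegative allocation weights per stage.
#' @param nCompounds number of compound features (>= 2).
#' @param stageEffect nonnegative scale \eqn{a} of stage-level separation.
#' @param originEffect nonnegative scale \eqn{c} of origin-level modulation.
#' @param noiseSd nonnegative per-sample noise scale \eqn{\sigma}.
#' @param baselineSd nonnegative scale \eqn{\sigma_b} of the shared baseline
#'   log profile (controls the correlation floor between unrelated samples).
#' @param seed integer seed; the table is bit-identical for a fixed
#'   configuration and seed, and the caller's RNG state is left untouched.
#' @return a \code{\linkS4class{PeakTable}}.
#' @examples
#' pt <- simulatePeakTable(nSamples = 24, nCompounds = 100, seed = 1)
#' table(sampleType(pt))
#' @export
simulatePeakTable <- function(nSamples = 140,
    stageLabels = c("unfermented", "fermented", "liquor"),
    originLabels = c("Brazil", "Cameroon", "Ecuador", "Ghana", "Indonesia",
                     "Ivory Coast", "Malaysia", "Tanzania"),
    originProportions = c(2, 2, 3, 1, 2, 4, 2, 2),
    stageProportions = rep(1, length(stageLabels)),
    nCompounds = 1000, stageEffect = 1, originEffect = 0.6,
    noiseSd = 0.8, baselineSd = 1, seed = NULL) {

    if (!is.numeric(nSamples) || nSamples < 2 || nSamples != round(nSamples))
        stop("'nSamples' must be an integer >= 2")
    if (!is.numeric(nCompounds) || nCompounds < 2 ||
        nCompounds != round(nCompounds))
        stop("'nCompounds' must be an integer >= 2")
    if (length(stageLabels) < 1L || length(originLabels) < 1L)
        stop("at least one stage and one origin label are required")
    if (anyDuplicated(stageLabels) || anyDuplicated(originLabels))
        stop("stage and origin labels must be unique")
    for (nm in c("stageEffect", "originEffect", "noiseSd", "baselineSd")) {
        v <- get(nm)
        if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
            stop(sprintf("'%s' must be a nonnegative number", nm))
    }
    if (length(originProportions) != length(originLabels) ||
        any(originProportions < 0) || sum(originProportions) <= 0)
        stop("'originProportions' must be nonnegative weights, one per ",
             "origin, with positive sum")
    if (length(stageProportions) != length(stageLabels) ||
        any(stageProportions < 0) || sum(stageProportions) <= 0)
        stop("'stageProportions' must be nonnegative weights, one per ",
             "stage, with positive sum")

    inv <- allocateInventory(nSamples, stageLabels, originLabels,
                             stageProportions, originProportions)
    p <- as.integer(nCompounds)
    nS <- length(stageLabels)
    nO <- length(originLabels)

    areas <- withSeed(seed, {
        baseline <- stats::rnorm(p, sd = baselineSd)
        u <- matrix(stats::rnorm(p * nS), p, nS)
        w <- array(stats::rnorm(p * nS * nO), dim = c(p, nS, nO))
        m <- matrix(0, p, nSamples)
        for (a in seq_len(nSamples)) {
            s <- inv$stageIdx[a]
            o <- inv$originIdx[a]
            m[, a] <- baseline + stageEffect * u[, s] +
                originEffect * w[, s, o] + noiseSd * stats::rnorm(p)
        }
        exp(m)
    })
    dimnames(areas) <- list(sprintf("compound_%04d", seq_len(p)),
                            sprintf("S%03d", seq_len(nSamples)))
    pt <- PeakTable(areas,
                    sampleType = stageLabels[inv$stageIdx],
                    origin = originLabels[inv$originIdx],
                    samplesInRows = FALSE)
    pt <- normalizeSampleSums(pt, total = 100)
    selectTopCompounds(pt, n = p)
}

# Deterministic largest-remainder allocation of samples to stage x origin
# cells; samples come out grouped by stage then origin.
allocateInventory <- function(nSamples, stageLabels, originLabels,
                              stageProportions, originProportions) {
    w <- outer(stageProportions, originProportions)
    w <- w / sum(w)
    target <- nSamples * w
    counts <- floor(target)
    short <- nSamples - sum(counts)
    if (short > 0) {
        rem <- target - counts
        ord <- order(as.vector(rem), decreasing = TRUE, method = "radix")
        counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
    }
    stageIdx <- integer(0)
    originIdx <- integer(0)
    for (s in seq_along(stageLabels))
        for (o in seq_along(originLabels)) {
            k <- counts[s, o]
            stageIdx <- c(stageIdx, rep.int(s, k))
            originIdx <- c(originIdx, rep.int(o, k))
        }
    list(stageIdx = stageIdx, originIdx = originIdx)
}
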