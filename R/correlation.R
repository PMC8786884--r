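#' Pairwise sample-sample correlation matrix
#'
#' Computes the matrix of correlations between every pair of LC-MS sample
#' profiles over the common compound set. For samples \eqn{\alpha, \beta} with
#' profiles \eqn{l^\alpha, l^\beta} the Pearson entry is
#' \deqn{r_{\alpha\beta} = \mathrm{cov}(l^\alpha, l^\beta) /
#'   (\sigma_{l^\alpha} \sigma_{l^\beta}),}
#' and the Spearman entry is the same quantity computed on the rank-transformed
#' profiles (ties receive average ranks). The population-vs-sample covariance
#' convention cancels in the ratio, so it does not matter here. Correlations
#' are computed jointly over all retained compounds; missing values must have
#' been resolved upstream (the reader maps them to 0).
#'
#' @param table a \code{\linkS4class{PeakTable}} with at least two compounds.
#' @param method \code{"spearman"} (default, the main analysis) or
#'   \code{"pearson"}.
#' @return a \code{\linkS4class{CorrelationMatrix}}.
#' @examples
#' pt <- simulatePeakTable(nSamples = 10, nCompounds = 50, seed = 1)
#' cm <- correlationMatrix(pt)
#' corValues(cm)[1:3, 1:3]
#' @export
correlationMatrix <- function(table, method = c("spearman", "pearson")) {
    stopifnot(methods::is(table, "PeakTable"))
    method <- match.arg(method)
    a <- peakAreas(table)
    if (nrow(a) < 2L) stop("need at least 2 compounds")
    sds <- apply(a, 2L, stats::sd)
    if (any(sds == 0))
        stop("sample(s) with constant profile (zero variance): ",
             paste(colnames(a)[sds == 0], collapse = ", "))
    v <- stats::cor(a, method = method)
    # guard against tiny asymmetries / overshoot from floating point
    v <- (v + t(v)) / 2
    v[v > 1] <- 1
    v[v < -1] <- -1
    diag(v) <- 1
    methods::new("CorrelationMatrix", values = v, method = method)
}

#' @describeIn correlationMatrix the correlation values (named square matrix).
#' @param x a CorrelationMatrix
#' @export
setMethod("corValues", "CorrelationMatrix", function(x) x@values)

#' @describeIn correlationMatrix the correlation method used.
#' @export
setMethod("corMethod", "CorrelationMatrix", function(x) x@method)

#' @describeIn correlationMatrix sample ids.
#' @export
setMethod("sampleIds", "CorrelationMatrix", function(x) rownames(x@values))

#' @describeIn correlationMatrix compact display.
#' @param object a CorrelationMatrix
#' @export
setMethod("show", "CorrelationMatrix", function(object) {
    v <- object@values
    off <- v[upper.tri(v)]
    cat(sprintf("CorrelationMatrix (%s): %d samples\n",
                object@method, nrow(v)))
    if (length(off))
        cat(sprintf("  off-diagonal range [%.3f, %.3f], %d positive pairs\n",
                    min(off), max(off), sum(off > 0)))
})

#' Export a correlation matrix to CSV
#'
#' Writes either the full square matrix (sample ids as header row and first
#' column, the layout correlation-heatmap tools consume) or a long format with
#' one row per unordered sample pair (\code{sample_a < sample_b} in sample
#' order).
#'
#' @param matrix a \code{\linkS4class{CorrelationMatrix}}.
#' @param path output CSV file.
#' @param layout \code{"square"} or \code{"long"}.
#' @param sortBy optional \code{\linkS4class{PeakTable}}; when given, samples
#'   in the square layout are sorted first by sample type and then by origin,
#'   the ordering that makes the block structure of the matrix visible.
#' @return invisibly, \code{path}.
#' @export
writeCorrelationMatrix <- function(matrix, path,
                                   layout = c("square", "long"),
                                   sortBy = NULL) {
    stopifnot(methods::is(matrix, "CorrelationMatrix"))
    layout <- match.arg(layout)
    v <- corValues(matrix)
    if (layout == "square") {
        if (!is.null(sortBy)) {
            stopifnot(methods::is(sortBy, "PeakTable"))
            ids <- sampleIds(sortBy)
            if (!setequal(ids, rownames(v)))
                stop("'sortBy' table and matrix cover different samples")
            ord <- ids[order(sampleType(sortBy), origin(sortBy),
                             method = "radix")]
            v <- v[ord, ord]
        }
        out <- data.frame(sample_id = rownames(v),
                          as.data.frame(v, check.names = FALSE),
                          check.names = FALSE)
        utils::write.csv(out, path, row.names = FALSE)
    } else {
        pr <- upperPairs(nrow(v))
        out <- data.frame(sample_a = rownames(v)[pr[, "i"]],
                          sample_b = rownames(v)[pr[, "j"]],
                          correlation = v[pr],
                          stringsAsFactors = FALSE)
        utils::write.csv(out, path, row.names = FALSE)
    }
    invisible(path)
}
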