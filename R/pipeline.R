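#' Configuration for an end-to-end pipeline run
#'
#' Collects every knob of the analysis in one validated list. Exactly one of
#' \code{input} (a peak-table file readable by \code{\link{readPeakTable}})
#' or \code{generator} (arguments for \code{\link{simulatePeakTable}}) must
#' be supplied.
#'
#' @param input optional path to a peak-table file (CSV or XLSX).
#' @param inputFormat \code{"csv"} or \code{"xlsx"}.
#' @param generator optional named list of \code{\link{simulatePeakTable}}
#'   arguments (its \code{seed} is supplied by the pipeline).
#' @param method correlation method; Spearman is the default for the main
#'   analysis, Pearson the variant.
#' @param nTopCompounds \code{"all"} or a compound count; around 1000 is the
#'   documented fast path for sweep statistics on large tables.
#' @param thresholds strictly increasing threshold grid in [0, 1].
#' @param nullReps null-ensemble size; 0 disables the ensemble.
#' @param radius majority-vote radius (1 or 2).
#' @param seed integer master seed; the generator consumes \code{seed} and
#'   the null ensemble \code{seed + 1}, so one number reproduces a full run.
#' @param outDir output directory (created if absent).
#' @return a validated config list of class \code{"pipelineConfig"}.
#' @seealso \code{\link{runPipeline}}
#' @export
pipelineConfig <- function(input = NULL, inputFormat = "csv",
                           generator = NULL,
                           method = c("spearman", "pearson"),
                           nTopCompounds = "all",
                           thresholds = seq(0, 0.9, by = 0.1),
                           nullReps = 100, radius = 1, seed = 1,
                           outDir = "sampleCorrNet-run") {
    method <- match.arg(method)
    if (is.null(input) == is.null(generator))
        stop("supply exactly one of 'input' or 'generator'")
    checkThresholds(thresholds)
    if (!is.numeric(nullReps) || nullReps < 0)
        stop("'nullReps' must be >= 0 (0 disables the null ensemble)")
    if (!identical(nTopCompounds, "all") &&
        (!is.numeric(nTopCompounds) || nTopCompounds < 1))
        stop("'nTopCompounds' must be \"all\" or a positive count")
    structure(list(input = input, inputFormat = inputFormat,
                   generator = generator, method = method,
                   nTopCompounds = nTopCompounds,
                   thresholds = as.numeric(thresholds),
                   nullReps = as.integer(nullReps),
                   radius = radius, seed = as.integer(seed),
                   outDir = outDir),
              class = "pipelineConfig")
}

#' Run the full correlation-network analysis pipeline
#'
#' Orchestrates the whole workflow: obtain the peak table (read or
#' simulate), normalize per-sample sums to 100, optionally restrict to the
#' most abundant compounds, compute the sample correlation matrix, sweep the
#' threshold grid, and write every artifact — correlation matrix (square and
#' long CSV), per-threshold edge lists, node attributes, size curve,
#' similarity curves with optional null-ensemble bands, accuracy curves, and
#' leave-one-out prediction grids with per-threshold mean scores for both the
#' sample-type and origin attributes. A manifest (JSON) records the
#' configuration, the seed, and an MD5 content hash of every artifact, so two
#' runs with the same inputs, config and seed produce hash-identical
#' manifests. Undefined statistics (no edges / no defined votes) are written
#' as empty cells, never as 0.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return invisibly, the manifest list.
#' @examples
#' cfg <- pipelineConfig(generator = list(nSamples = 12, nCompounds = 40),
#'                       thresholds = seq(0, 0.8, 0.2), nullReps = 10,
#'                       seed = 42, outDir = tempfile())
#' manifest <- runPipeline(cfg)
#' names(manifest$files)
#' @export
runPipeline <- function(config) {
    if (!inherits(config, "pipelineConfig"))
        stop("'config' must come from pipelineConfig()")
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    out <- function(...) file.path(config$outDir, ...)

    pt <- if (!is.null(config$input)) {
        readPeakTable(config$input, format = config$inputFormat)
    } else {
        do.call(simulatePeakTable,
                c(config$generator, list(seed = config$seed)))
    }
    pt <- normalizeSampleSums(pt, total = 100)
    if (!identical(config$nTopCompounds, "all"))
        pt <- selectTopCompounds(pt, min(config$nTopCompounds, nrow(pt)))

    cm <- correlationMatrix(pt, method = config$method)
    labels <- list(sample_type = sampleType(pt), origin = origin(pt))

    files <- character(0)
    writePeakTable(pt, out("peak_table.csv"))
    writeNodeAttributes(pt, out("node_attributes.csv"))
    writeCorrelationMatrix(cm, out("correlation_matrix.csv"),
                           layout = "square", sortBy = pt)
    writeCorrelationMatrix(cm, out("correlation_long.csv"), layout = "long")
    files <- c("peak_table.csv", "node_attributes.csv",
               "correlation_matrix.csv", "correlation_long.csv")

    nets <- sweepNetworks(cm, config$thresholds)
    dir.create(out("networks"), showWarnings = FALSE)
    for (k in seq_along(nets)) {
        f <- sprintf("networks/edges_t%s.csv", names(nets)[k])
        exportNetwork(nets[[k]], out(f), format = "edge-csv")
        files <- c(files, f)
    }
    utils::write.csv(sizeCurve(nets), out("size_curve.csv"),
                     row.names = FALSE)
    files <- c(files, "size_curve.csv")

    sim <- similarityCurves(cm, labels, config$thresholds)
    if (config$nullReps > 0) {
        nul <- nullEnsemble(cm, labels, config$thresholds,
                            nReps = config$nullReps,
                            seed = config$seed + 1L)
        sim <- merge(sim, nul, by = c("threshold", "attribute"), sort = FALSE)
        sim <- sim[order(sim$attribute, sim$threshold), ]
    }
    utils::write.csv(sim, out("similarity_curves.csv"),
                     row.names = FALSE, na = "")
    files <- c(files, "similarity_curves.csv")

    acc <- rbind(
        accuracyCurve(cm, labels$sample_type, config$thresholds,
                      attribute = "sample_type"),
        accuracyCurve(cm, labels$origin, config$thresholds,
                      attribute = "origin"))
    utils::write.csv(acc, out("accuracy_curves.csv"), row.names = FALSE)
    files <- c(files, "accuracy_curves.csv")

    scores <- list()
    for (attr in names(labels)) {
        g <- predictionGrid(cm, labels[[attr]], config$thresholds,
                            attribute = attr, radius = config$radius)
        f <- sprintf("prediction_grid_%s.csv", attr)
        gridDf <- data.frame(sample_id = rownames(voteOutcomes(g)),
                             as.data.frame(voteOutcomes(g),
                                           check.names = FALSE),
                             check.names = FALSE)
        utils::write.csv(gridDf, out(f), row.names = FALSE)
        files <- c(files, f)
        sc <- meanPredictionScore(g)
        sc$attribute <- attr
        scores[[attr]] <- sc
    }
    utils::write.csv(do.call(rbind, scores), out("prediction_scores.csv"),
                     row.names = FALSE, na = "")
    files <- c(files, "prediction_scores.csv")

    hashes <- as.character(tools::md5sum(file.path(config$outDir, files)))
    manifest <- list(
        package = "sampleCorrNet",
        config = unclass(config),
        n_samples = ncol(pt),
        n_compounds = nrow(pt),
        files = stats::setNames(as.list(hashes), files))
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}
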