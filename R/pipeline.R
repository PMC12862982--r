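#' Graph-based clustering of spots
#'
#' Builds a shared-nearest-neighbor graph on a PCA of the chosen assay
#' (delegated to [scran::buildSNNGraph()]) and partitions it with the Leiden
#' algorithm ([igraph::cluster_leiden()], modularity objective). The seed
#' controls both the PCA-independent graph construction and the Leiden
#' refinement, so identical inputs and seeds give identical labels.
#'
#' @param x a [SpotExperiment-class].
#' @param assayName assay to cluster on (e.g. `"logcounts"` or `"imputed"`).
#' @param nPCs number of principal components (default 20, capped at the
#'   matrix rank).
#' @param snnK neighbors for the SNN graph (default 15).
#' @param resolution Leiden resolution parameter (default 1).
#' @param seed integer seed.
#' @return integer vector of cluster labels, one per spot.
#' @examples
#' se <- simulateSpatialData(nSpots = 100, nGenes = 30, seed = 1)
#' se <- normalizeLog1p(se)
#' table(clusterSpots(se, "logcounts", seed = 1))
#' @export
clusterSpots <- function(x, assayName = "logcounts", nPCs = 20, snnK = 15,
                         resolution = 1, seed = 0) {
    mat <- as.matrix(SummarizedExperiment::assay(x, assayName))
    nPCs <- min(nPCs, nrow(mat) - 1L, ncol(mat) - 1L)
    .withSeed(seed, {
        pcs <- stats::prcomp(t(mat), rank. = nPCs, center = TRUE,
                             scale. = FALSE)$x
        graph <- scran::buildSNNGraph(t(pcs), k = snnK, d = NA)
        cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                                     resolution = resolution,
                                     n_iterations = 5)
        as.integer(igraph::membership(cl))
    })
}

#' End-to-end imputation pipeline
#'
#' @description
#' Runs the full workflow in fixed order on a raw-count
#' [SpotExperiment-class]: quality control -> total-count/log1p normalization
#' -> highly-variable-gene selection -> spatially aware dropout imputation ->
#' Leiden clustering -> clustering-agreement evaluation against ground-truth
#' domains (when present). Imputation always runs on the normalized,
#' gene-selected matrix, never on raw counts.
#'
#' With `compareBaseline = TRUE` the same clustering (same configuration and
#' seed) is also run on the un-imputed normalized matrix, giving a paired
#' before/after comparison of the downstream metrics.
#'
#' @param x a [SpotExperiment-class] with raw counts and spatial coordinates.
#' @param qc named list of [qcFilter()] arguments, or `NULL` to skip QC (for
#'   data already filtered).
#' @param targetSum passed to [normalizeLog1p()].
#' @param hvgMode passed to [selectHVG()] (`"all"`, `"top2000"`, `"top5000"`).
#' @param k,delta imputation configuration, see [spaMeanImpute()].
#' @param sequential passed to [spaMeanImpute()].
#' @param nPCs,snnK,resolution clustering configuration, see [clusterSpots()].
#' @param seed integer seed for the clustering stage.
#' @param compareBaseline also cluster the un-imputed matrix (default `TRUE`).
#' @return list with elements `se` (the processed SpotExperiment, carrying
#'   assays `logcounts`, `imputed`, `decision` and the imputation report in
#'   its metadata), `clusters` (integer labels on the imputed matrix),
#'   `metrics` (named vector ari/nmi/ami/homo, or `NULL` without ground
#'   truth), `report` (the [ImputationReport-class]), and — when requested —
#'   `baselineClusters` and `baselineMetrics` for the un-imputed matrix.
#' @examples
#' se <- simulateSpatialData(nSpots = 200, nGenes = 40, seed = 7)
#' out <- runPipeline(se, qc = list(minCounts = 1, maxCounts = 1e9,
#'                                  minCells = 1), seed = 7)
#' out$metrics
#' @export
runPipeline <- function(x, qc = list(), targetSum = "median",
                        hvgMode = "all", k = 6, delta = 0.4,
                        sequential = FALSE, nPCs = 20, snnK = 15,
                        resolution = 1, seed = 0, compareBaseline = TRUE) {
    if (is.null(spatialCoords(x)))
        stop("pipeline stage 'impute' requires spatial coordinates ",
             "[stage=input, code=missing_coords]")
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
                 " [stage=", name, "]", call. = FALSE))
    }
    if (!is.null(qc))
        x <- stage("qc", do.call(qcFilter, c(list(x), qc)))
    x <- stage("normalize", normalizeLog1p(x, targetSum = targetSum))
    x <- stage("hvg", selectHVG(x, mode = hvgMode))
    x <- stage("impute", spaMeanImpute(x, k = k, delta = delta,
                                       sequential = sequential))
    clusters <- stage("cluster",
        clusterSpots(x, assayName = "imputed", nPCs = nPCs, snnK = snnK,
                     resolution = resolution, seed = seed))
    truth <- domainLabels(x)
    metrics <- if (!is.null(truth))
        stage("evaluate", clusteringMetrics(truth, clusters))
    out <- list(se = x, clusters = clusters, metrics = metrics,
                report = S4Vectors::metadata(x)$imputation_report)
    if (compareBaseline) {
        base <- stage("cluster",
            clusterSpots(x, assayName = "logcounts", nPCs = nPCs,
                         snnK = snnK, resolution = resolution, seed = seed))
        out$baselineClusters <- base
        out$baselineMetrics <- if (!is.null(truth))
            clusteringMetrics(truth, base)
    }
    out
}
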