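#' Quality-control filtering of spots and genes
#'
#' Standard SRT quality control applied in a fixed order: (1) spots with total
#' counts below `minCounts` or above `maxCounts` are removed (likely empty or
#' doublet-containing barcodes); (2) spots whose mitochondrial count fraction
#' exceeds `maxMitoPct` are removed (unhealthy or dying cells); (3) genes
#' detected (non-zero) in fewer than `minCells` of the remaining spots are
#' removed. Coordinates and annotations are subset in lockstep, and a report
#' of counts removed at each step is stored in `metadata(x)$qc_report`.
#'
#' Mitochondrial genes are identified by a case-insensitive gene-name prefix
#' match (default `"MT-"`).
#'
#' @param x a [SpotExperiment-class] holding raw counts (not yet normalized).
#' @param minCounts,maxCounts per-spot total-count bounds (defaults 50 and
#'   35000, the permissive end of common SRT settings).
#' @param maxMitoPct maximum mitochondrial percentage per spot (default 20).
#' @param minCells minimum number of spots a gene must be detected in
#'   (default 10).
#' @param mitoPrefix gene-name prefix marking mitochondrial genes.
#' @return the filtered SpotExperiment with `metadata(x)$qc_report` set.
#' @examples
#' se <- simulateSpatialData(nSpots = 100, nGenes = 30, seed = 1)
#' se <- qcFilter(se, minCounts = 1, maxCounts = 1e6, minCells = 2)
#' S4Vectors::metadata(se)$qc_report
#' @export
qcFilter <- function(x, minCounts = 50, maxCounts = 35000, maxMitoPct = 20,
                     minCells = 10, mitoPrefix = "MT-") {
    if (minCounts >= maxCounts)
        stop("'minCounts' must be smaller than 'maxCounts'")
    if (isTRUE(S4Vectors::metadata(x)$normalized))
        stop("qcFilter() expects raw counts; this object is already normalized")
    counts <- SummarizedExperiment::assay(x, "counts")
    nSpots0 <- ncol(x); nGenes0 <- nrow(x)

    totals <- Matrix::colSums(counts)
    lowCount <- totals < minCounts
    highCount <- totals > maxCounts
    keepSpot <- !(lowCount | highCount)
    if (!any(keepSpot))
        stop("all spots removed by the total-count filter (minCounts = ",
             minCounts, ", maxCounts = ", maxCounts, ")")
    x1 <- x[, keepSpot]

    counts1 <- SummarizedExperiment::assay(x1, "counts")
    isMito <- startsWith(toupper(rownames(x1)), toupper(mitoPrefix))
    mitoPct <- if (any(isMito)) {
        100 * Matrix::colSums(counts1[isMito, , drop = FALSE]) /
            Matrix::colSums(counts1)
    } else rep(0, ncol(x1))
    keepMito <- mitoPct <= maxMitoPct
    if (!any(keepMito))
        stop("all spots removed by the mitochondrial filter (maxMitoPct = ",
             maxMitoPct, ")")
    x2 <- x1[, keepMito]

    counts2 <- SummarizedExperiment::assay(x2, "counts")
    detected <- Matrix::rowSums(counts2 != 0)
    keepGene <- detected >= minCells
    if (!any(keepGene))
        stop("all genes removed by the min-cells filter (minCells = ",
             minCells, ")")
    x3 <- x2[keepGene, ]

    S4Vectors::metadata(x3)$qc_report <- list(
        n_spots_in = nSpots0,
        n_removed_low_counts = sum(lowCount),
        n_removed_high_counts = sum(highCount),
        n_removed_mito = sum(!keepMito),
        n_spots_out = ncol(x3),
        n_genes_in = nGenes0,
        n_removed_genes_min_cells = sum(!keepGene),
        n_genes_out = nrow(x3),
        config = list(min_counts = minCounts, max_counts = maxCounts,
                      max_mito_pct = maxMitoPct, min_cells = minCells,
                      mito_prefix = mitoPrefix))
    x3
}

#' Total-count normalization followed by log1p
#'
#' @description
#' Scales each spot (column) so its total equals `targetSum` — or, with
#' `targetSum = "median"`, the median of the pre-scaling spot totals — then
#' replaces every entry x by `log(1 + x)`. Zero entries remain exactly zero,
#' which the downstream zero indexing relies on.
#'
#' @param x genes x spots matrix of raw counts, or a [SpotExperiment-class].
#' @param targetSum positive number, or `"median"` (default).
#' @param ... passed between methods.
#' @return For a matrix: the normalized matrix. For a SpotExperiment: the
#'   object with a `"logcounts"` assay added and `metadata(x)$normalized`
#'   set to `TRUE`.
#' @examples
#' m <- cbind(a = c(0, 2, 2), b = c(1, 1, 2))
#' normalizeLog1p(m, targetSum = 4)
#' @rdname normalizeLog1p
#' @export
setMethod("normalizeLog1p", "matrix", function(x, targetSum = "median", ...) {
    totals <- colSums(x)
    if (any(totals == 0))
        stop(sum(totals == 0), " spot(s) have zero total counts; ",
             "run qcFilter() first")
    ts <- if (identical(targetSum, "median")) stats::median(totals)
          else as.numeric(targetSum)
    if (!is.finite(ts) || ts <= 0)
        stop("'targetSum' must be a positive number or \"median\"")
    log1p(sweep(x, 2, totals / ts, "/"))
})

#' @rdname normalizeLog1p
#' @export
setMethod("normalizeLog1p", "SpotExperiment",
    function(x, targetSum = "median", ...) {
    if (isTRUE(S4Vectors::metadata(x)$normalized))
        stop("object is already normalized")
    counts <- as.matrix(SummarizedExperiment::assay(x, "counts"))
    SummarizedExperiment::assay(x, "logcounts") <-
        normalizeLog1p(counts, targetSum = targetSum)
    S4Vectors::metadata(x)$normalized <- TRUE
    S4Vectors::metadata(x)$target_sum <-
        if (identical(targetSum, "median")) stats::median(colSums(counts))
        else as.numeric(targetSum)
    x
})

# Dispersion ranking: per-gene dispersion (variance/mean) of the
# log-normalized values. No per-bin re-standardization: on panel-sized data
# with distinct gene programs, mean bins become homogeneous and any in-bin
# normalization erases exactly the between-program contrast the selection is
# meant to keep.
.hvgRank <- function(logmat) {
    mu <- rowMeans(logmat)
    v <- apply(logmat, 1, stats::var)
    disp <- ifelse(mu > 0, v / mu, -Inf)
    disp
}

#' Highly-variable-gene selection
#'
#' @description
#' Ranks genes by dispersion (variance/mean of the log-normalized values) and
#' retains the top N in their original row order. `mode` gives the three standard feature
#' settings: the top 2000 or 5000 most variable genes, or all genes
#' (identity). When fewer than N genes are present the input is returned
#' unchanged. Ties are broken by original gene order (first kept first).
#'
#' @param x genes x spots log-normalized matrix, or a [SpotExperiment-class]
#'   with a `"logcounts"` assay.
#' @param mode `"all"`, `"top2000"` or `"top5000"`.
#' @param n optional explicit number of genes, overriding `mode`.
#' @param ... passed between methods.
#' @return the input with only the selected gene rows, original order kept.
#' @examples
#' se <- simulateSpatialData(nSpots = 100, nGenes = 50, seed = 1)
#' se <- normalizeLog1p(se)
#' nrow(selectHVG(se, n = 10))
#' @rdname selectHVG
#' @export
setMethod("selectHVG", "matrix",
    function(x, mode = c("all", "top2000", "top5000"), n = NULL, ...) {
    if (is.null(n)) {
        mode <- match.arg(mode)
        if (mode == "all") return(x)
        n <- if (mode == "top2000") 2000L else 5000L
    }
    if (nrow(x) <= n) return(x)
    z <- .hvgRank(x)
    top <- order(-z, seq_along(z))[seq_len(n)]   # ties: first gene kept first
    x[sort(top), , drop = FALSE]                 # original column order
})

#' @rdname selectHVG
#' @export
setMethod("selectHVG", "SpotExperiment",
    function(x, mode = c("all", "top2000", "top5000"), n = NULL, ...) {
    if (!isTRUE(S4Vectors::metadata(x)$normalized))
        stop("dispersion ranking needs log-normalized data; ",
             "run normalizeLog1p() first")
    if (is.null(n)) {
        mode <- match.arg(mode)
        if (mode == "all") return(x)
        n <- if (mode == "top2000") 2000L else 5000L
    }
    if (nrow(x) <= n) return(x)
    z <- .hvgRank(as.matrix(SummarizedExperiment::assay(x, "logcounts")))
    top <- order(-z, seq_along(z))[seq_len(n)]
    x[sort(top), ]
})
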