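#' @title ImputationReport: dropout accounting for one imputation run
#'
#' @description
#' Per-entry bookkeeping of how the imputer classified the zero entries of the
#' expression matrix: imputed dropouts, retained biological zeros (zero ratio
#' above the threshold), and skipped entries whose whole neighborhood is zero.
#' The sparsity identity
#' `zeroSparsityBefore - zeroSparsityAfter == dropoutDetectedPct` always holds.
#'
#' @slot nZeroCandidates integer, zero entries considered.
#' @slot nImputed integer, entries replaced by a neighbor mean.
#' @slot nRetainedBiological integer, zeros kept because zero ratio > delta.
#' @slot nSkippedAllZero integer, zeros kept because every neighbor is zero.
#' @slot zeroSparsityBefore percentage of exactly-zero entries before.
#' @slot zeroSparsityAfter percentage after.
#' @slot dropoutDetectedPct percentage of entries detected as dropout and
#'   imputed (before minus after).
#' @slot k,delta the configuration used.
#'
#' @exportClass ImputationReport
setClass("ImputationReport",
    representation(
        nZeroCandidates = "integer",
        nImputed = "integer",
        nRetainedBiological = "integer",
        nSkippedAllZero = "integer",
        zeroSparsityBefore = "numeric",
        zeroSparsityAfter = "numeric",
        dropoutDetectedPct = "numeric",
        k = "integer",
        delta = "numeric"))

setValidity("ImputationReport", function(object) {
    msg <- NULL
    tot <- object@nImputed + object@nRetainedBiological + object@nSkippedAllZero
    if (tot != object@nZeroCandidates)
        msg <- c(msg, "decision counts must sum to the zero-candidate count")
    if (object@dropoutDetectedPct < -1e-12)
        msg <- c(msg, "dropoutDetectedPct must be non-negative")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "ImputationReport", function(object) {
    cat("ImputationReport (k =", object@k, ", delta =", object@delta, ")\n")
    cat(sprintf("  zero candidates      : %d\n", object@nZeroCandidates))
    cat(sprintf("  imputed dropouts     : %d\n", object@nImputed))
    cat(sprintf("  retained biological  : %d\n", object@nRetainedBiological))
    cat(sprintf("  skipped (all-zero NN): %d\n", object@nSkippedAllZero))
    cat(sprintf("  zero sparsity        : %.3f%% -> %.3f%% (dropout detected %.3f%%)\n",
                object@zeroSparsityBefore, object@zeroSparsityAfter,
                object@dropoutDetectedPct))
})

#' Coerce an ImputationReport to a list
#'
#' Convenience for JSON serialization of reports.
#'
#' @param x an [ImputationReport-class].
#' @param ... ignored.
#' @return a named list of the report fields.
#' @export
#' @method as.list ImputationReport
as.list.ImputationReport <- function(x, ...) {
    list(n_zero_candidates = x@nZeroCandidates,
         n_imputed = x@nImputed,
         n_retained_biological = x@nRetainedBiological,
         n_skipped_allzero_neighborhood = x@nSkippedAllZero,
         zero_sparsity_before_pct = x@zeroSparsityBefore,
         zero_sparsity_after_pct = x@zeroSparsityAfter,
         dropout_detected_pct = x@dropoutDetectedPct,
         k = x@k, delta = x@delta)
}

#' Remove genes with zero expression across all spots
#'
#' Genes that are zero at every spot carry no information for
#' neighborhood-based imputation (their zero ratio is always 1) and are removed
#' before zero indexing.
#'
#' @param x genes x spots matrix.
#' @return list with `matrix` (retained genes, original order) and `removed`
#'   (integer indices of dropped genes; named when `x` has rownames).
#' @examples
#' m <- rbind(a = c(1, 0), b = c(0, 0))
#' dropAllZeroGenes(m)$removed
#' @export
dropAllZeroGenes <- function(x) {
    keep <- Matrix::rowSums(x != 0) > 0
    if (!any(keep))
        stop("all genes are zero across all spots; nothing to impute")
    removed <- which(!keep)
    list(matrix = x[keep, , drop = FALSE], removed = removed)
}

#' Per-spot indices of zero-valued genes
#'
#' For each spot i, the set of gene row indices j with `x[j, i] == 0` exactly
#' (no tolerance: log1p normalization maps true zeros to exact zeros). All-zero
#' genes must be removed first (see [dropAllZeroGenes()]).
#'
#' @param x genes x spots matrix with no all-zero gene.
#' @return list of length `ncol(x)`; element i is an integer vector of zero
#'   gene indices for spot i.
#' @examples
#' m <- cbind(c(0, 1.2, 0), c(1, 1, 1))
#' indexZeros(m)
#' @export
indexZeros <- function(x) {
    if (any(Matrix::rowSums(x != 0) == 0))
        stop("all-zero genes present; run dropAllZeroGenes() first")
    x <- as.matrix(x)
    lapply(seq_len(ncol(x)), function(i) which(x[, i] == 0))
}

#' K nearest spatial neighbors of every spot
#'
#' Exact Euclidean nearest neighbors on the 2D spot coordinates, self excluded,
#' sorted by ascending distance with ties broken by ascending spot index. The
#' result is deterministic regardless of how the search is organized.
#'
#' @param coords n_spots x 2 numeric matrix.
#' @param k number of neighbors requested; reduced to `n - 1` with a warning
#'   when `k >= n`.
#' @return integer matrix, `n x min(k, n - 1)`; row i lists the neighbors of
#'   spot i nearest-first. The realized k is `ncol()` of the result.
#' @examples
#' xy <- cbind(c(0, 1, 3), 0)
#' buildNeighborIndex(xy, k = 1)
#' @export
buildNeighborIndex <- function(coords, k) {
    coords <- as.matrix(coords)
    n <- nrow(coords)
    if (n < 2L)
        stop("at least 2 spots are required to define neighbors")
    if (ncol(coords) != 2L)
        stop("'coords' must be n x 2")
    if (k < 1L)
        stop("'k' must be a positive integer")
    kEff <- as.integer(min(k, n - 1L))
    if (kEff < k)
        warning("k = ", k, " >= n spots; reduced to ", kEff)
    d <- as.matrix(stats::dist(coords))
    nb <- matrix(0L, nrow = n, ncol = kEff)
    idx <- seq_len(n)
    for (i in idx) {
        ord <- order(d[i, ], idx)      # distance, then ascending index
        ord <- ord[ord != i]           # self excluded
        nb[i, ] <- ord[seq_len(kEff)]
    }
    nb
}

#' Zero ratio of one gene in one spot's neighborhood
#'
#' Fraction of a spot's spatial neighbors at which the gene is also exactly
#' zero. Low values suggest a technical dropout (the gene is expressed nearby);
#' high values suggest a true biological zero. The denominator is the realized
#' neighbor count `ncol(neighbors)`.
#'
#' @param x genes x spots matrix.
#' @param neighbors neighbor index from [buildNeighborIndex()].
#' @param spot spot (column) index.
#' @param gene gene (row) index; the entry `x[gene, spot]` is expected to be 0.
#' @return numeric in \[0, 1\].
#' @examples
#' x <- rbind(g = c(0, 0, 0, 2, 3, 0))
#' nb <- matrix(2:6, nrow = 1)  # neighbors of spot 1
#' zeroRatio(x, nb, spot = 1, gene = 1)  # 3/5
#' @export
zeroRatio <- function(x, neighbors, spot, gene) {
    nbv <- x[gene, neighbors[spot, ]]
    sum(nbv == 0) / ncol(neighbors)
}

# Frozen-snapshot core: every read comes from the input matrix, so the result
# does not depend on the order in which spots are visited.
.imputeFrozen <- function(x, nb, delta) {
    n <- ncol(x)
    kEff <- ncol(nb)
    A <- Matrix::sparseMatrix(i = as.vector(nb),
                              j = rep(seq_len(n), kEff),
                              x = 1, dims = c(n, n))
    xm <- as.matrix(x)
    nz <- xm != 0
    S <- as.matrix(xm %*% A)          # neighbor value sums per (gene, spot)
    C <- as.matrix(nz %*% A)          # non-zero neighbor counts
    ratio <- (kEff - C) / kEff
    isZero <- !nz
    impute <- isZero & ratio <= delta & C > 0
    skipped <- isZero & ratio <= delta & C == 0
    retained <- isZero & ratio > delta
    out <- xm
    out[impute] <- S[impute] / C[impute]
    decision <- matrix(0L, nrow(xm), ncol(xm), dimnames = dimnames(xm))
    decision[impute] <- 1L
    decision[retained] <- 2L
    decision[skipped] <- 3L
    list(out = out, decision = decision)
}

# Sequential alternative: spots are visited in column order and imputed values
# are written back immediately, so later spots can read earlier imputations.
.imputeSequential <- function(x, nb, delta) {
    xm <- as.matrix(x)
    kEff <- ncol(nb)
    decision <- matrix(0L, nrow(xm), ncol(xm), dimnames = dimnames(xm))
    for (i in seq_len(ncol(xm))) {
        zi <- which(xm[, i] == 0)
        if (!length(zi)) next
        nbv <- xm[zi, nb[i, ], drop = FALSE]
        nzc <- rowSums(nbv != 0)
        ratio <- (kEff - nzc) / kEff
        valid <- ratio <= delta
        imp <- valid & nzc > 0
        skp <- valid & nzc == 0
        decision[zi[imp], i] <- 1L
        decision[zi[!valid], i] <- 2L
        decision[zi[skp], i] <- 3L
        if (any(imp))
            xm[zi[imp], i] <- rowSums(nbv[imp, , drop = FALSE]) / nzc[imp]
    }
    list(out = xm, decision = decision)
}

#' Spatially aware dropout imputation
#'
#' @description
#' Classifies every zero entry of a normalized spot-gene matrix as technical
#' dropout or biological zero using the spot's k nearest spatial neighbors,
#' and imputes the dropouts with the mean of the non-zero neighbor values.
#'
#' For a zero entry (gene j, spot i), the zero ratio is the fraction of the k
#' neighbors at which gene j is also zero. If the ratio is at most `delta`
#' (inclusive) and at least one neighbor expresses the gene, the entry is
#' replaced by the arithmetic mean of the neighbors' non-zero values of gene j.
#' If the ratio exceeds `delta`, the zero is retained as biological. If every
#' neighbor is zero (possible only when `delta = 1`), the entry is skipped.
#' Non-zero entries are never modified.
#'
#' By default all reads come from a frozen snapshot of the input, so the result
#' is independent of spot visiting order; `sequential = TRUE` switches to
#' in-place updates where later spots can see earlier imputations.
#'
#' Genes that are zero across all spots are removed first (with a warning when
#' any are present); the returned matrix covers the retained genes.
#'
#' @param x genes x spots matrix of log-normalized expression, or a
#'   [SpotExperiment-class] carrying a `"logcounts"` assay.
#' @param coords n_spots x 2 coordinate matrix (matrix method only; the
#'   SpotExperiment method uses `spatialCoords(x)`).
#' @param k neighbors per spot; default 6, the contact number of a hexagonal
#'   spot lattice.
#' @param delta dropout threshold in \[0, 1\]; zero ratio <= delta qualifies
#'   for imputation. Default 0.4.
#' @param sequential logical; use in-place sequential updates instead of the
#'   frozen-snapshot semantics. Default `FALSE`.
#' @param assayName assay to impute (SpotExperiment method); default
#'   `"logcounts"`.
#' @param ... passed between methods.
#'
#' @return For a matrix: a list with `imputed` (matrix), `report`
#'   ([ImputationReport-class]) and `decision` (integer matrix; 0 = non-zero
#'   entry untouched, 1 = imputed dropout, 2 = retained biological zero,
#'   3 = skipped, all-zero neighborhood). For a SpotExperiment: the object
#'   with added assays `"imputed"` and `"decision"` and the report in
#'   `metadata(x)$imputation_report`.
#'
#' @examples
#' se <- simulateSpatialData(nSpots = 100, nGenes = 30, seed = 1)
#' se <- normalizeLog1p(se)
#' se <- spaMeanImpute(se, k = 6, delta = 0.4)
#' S4Vectors::metadata(se)$imputation_report
#'
#' @export
setMethod("spaMeanImpute", "matrix",
    function(x, coords, k = 6, delta = 0.4, sequential = FALSE, ...) {
    coords <- as.matrix(coords)
    if (nrow(coords) != ncol(x))
        stop("'coords' rows (", nrow(coords),
             ") must match the number of spots (", ncol(x), ")")
    if (delta < 0 || delta > 1)
        stop("'delta' must lie in [0, 1]")
    dz <- dropAllZeroGenes(x)
    if (length(dz$removed))
        warning(length(dz$removed), " all-zero gene(s) removed before imputation")
    xm <- as.matrix(dz$matrix)
    nb <- buildNeighborIndex(coords, k)
    res <- if (sequential) .imputeSequential(xm, nb, delta)
           else .imputeFrozen(xm, nb, delta)
    before <- 100 * sum(xm == 0) / length(xm)
    after <- 100 * sum(res$out == 0) / length(res$out)
    report <- methods::new("ImputationReport",
        nZeroCandidates = sum(res$decision != 0L),
        nImputed = sum(res$decision == 1L),
        nRetainedBiological = sum(res$decision == 2L),
        nSkippedAllZero = sum(res$decision == 3L),
        zeroSparsityBefore = before,
        zeroSparsityAfter = after,
        dropoutDetectedPct = before - after,
        k = ncol(nb), delta = as.numeric(delta))
    list(imputed = res$out, report = report, decision = res$decision,
         removedGenes = dz$removed)
})

#' @rdname spaMeanImpute
#' @export
setMethod("spaMeanImpute", "SpotExperiment",
    function(x, k = 6, delta = 0.4, sequential = FALSE,
             assayName = "logcounts", ...) {
    if (is.null(spatialCoords(x)))
        stop("this SpotExperiment has no 'spatial' coordinates; ",
             "imputation requires spot positions")
    if (!assayName %in% SummarizedExperiment::assayNames(x))
        stop("assay '", assayName, "' not found; run normalizeLog1p() first")
    if (!isTRUE(S4Vectors::metadata(x)$normalized))
        stop("matrix is not normalized; run normalizeLog1p() first")
    mat <- as.matrix(SummarizedExperiment::assay(x, assayName))
    res <- spaMeanImpute(mat, spatialCoords(x), k = k, delta = delta,
                         sequential = sequential)
    if (length(res$removedGenes))
        x <- x[-res$removedGenes, ]
    SummarizedExperiment::assay(x, "imputed") <- res$imputed
    SummarizedExperiment::assay(x, "decision") <- res$decision
    S4Vectors::metadata(x)$imputation_report <- res$report
    x
})
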