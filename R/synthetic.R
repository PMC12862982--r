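# Evaluate expr under a local seed, restoring the caller's RNG state after.
# expr is a promise with the caller's environment, so evaluation happens there.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

#' Lay out spots on a lattice and partition them into spatial domains
#'
#' Builds a near-square lattice of `nSpots` points (square grid, or a
#' hexagonal lattice with offset rows as on Visium slides) and partitions it
#' into `nDomains` spatially contiguous bands of near-equal size, emulating
#' layered tissue such as cortical laminae. Spots are sorted by (x, y) and cut
#' into contiguous chunks, so every domain is connected under the lattice
#' 4-neighborhood; the assignment of labels to bands is shuffled by `seed`.
#'
#' @param nSpots number of spots.
#' @param layout `"grid"` (unit square lattice) or `"hex"` (odd rows offset by
#'   0.5, row spacing sqrt(3)/2).
#' @param nDomains number of domains; must not exceed `nSpots`.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return list with `coords` (nSpots x 2 matrix, unique rows) and `labels`
#'   (integer vector in `[0, nDomains)`).
#' @examples
#' d <- generateDomains(100, nDomains = 4, seed = 1)
#' table(d$labels)
#' @export
generateDomains <- function(nSpots, layout = c("grid", "hex"), nDomains = 4,
                            seed = NULL) {
    layout <- match.arg(layout)
    if (nDomains > nSpots)
        stop("'nDomains' (", nDomains, ") cannot exceed 'nSpots' (", nSpots, ")")
    if (nDomains < 1L || nSpots < 1L)
        stop("'nSpots' and 'nDomains' must be positive")
    ncols <- ceiling(sqrt(nSpots))
    idx <- seq_len(nSpots) - 1L
    col <- idx %% ncols
    row <- idx %/% ncols
    if (layout == "hex") {
        coords <- cbind(x = col + 0.5 * (row %% 2), y = row * sqrt(3) / 2)
    } else {
        coords <- cbind(x = as.numeric(col), y = as.numeric(row))
    }
    ord <- order(coords[, 1], coords[, 2])
    sizes <- rep(nSpots %/% nDomains, nDomains)
    extra <- nSpots %% nDomains
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    band <- rep(seq_len(nDomains), times = sizes)
    perm <- .withSeed(seed, sample.int(nDomains))
    labels <- integer(nSpots)
    labels[ord] <- perm[band] - 1L
    list(coords = coords, labels = labels)
}

#' Simulate domain-structured count expression
#'
#' Draws negative-binomial counts for `nGenes` genes over the spots described
#' by `labels`. Each domain owns a disjoint block of `markersPerDomain` marker
#' genes whose mean is `baseMean * markerFold` inside the domain and
#' `baseMean` elsewhere; all remaining genes have mean `baseMean` everywhere.
#' The negative-binomial size parameter is `1 / dispersion`, so
#' `Var = mu + dispersion * mu^2`.
#'
#' @param labels per-spot integer domain labels in `[0, D)`.
#' @param nGenes total genes; must be at least `markersPerDomain * D`.
#' @param markersPerDomain marker genes per domain (disjoint blocks, genes
#'   `d * markersPerDomain + (1:markersPerDomain)` for domain d). The default
#'   gives each domain a program of 10% of the panel, emulating a targeted
#'   panel enriched for domain-discriminating genes.
#' @param baseMean background negative-binomial mean.
#' @param markerFold fold change of a marker inside its own domain (> 1 for a
#'   real signal; 1 is the no-signal limit).
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param seed integer seed, or `NULL`.
#' @return genes x spots integer count matrix with dimnames.
#' @examples
#' d <- generateDomains(100, nDomains = 4, seed = 1)
#' m <- generateExpression(d$labels, nGenes = 50, seed = 1)
#' dim(m)
#' @export
generateExpression <- function(labels, nGenes,
                               markersPerDomain = max(1L, floor(0.1 * nGenes)),
                               baseMean = 2, markerFold = 5, dispersion = 1,
                               seed = NULL) {
    doms <- sort(unique(labels))
    D <- length(doms)
    if (markersPerDomain * D > nGenes)
        stop("marker blocks (", markersPerDomain * D,
             " genes) exceed 'nGenes' (", nGenes, ")")
    if (baseMean <= 0 || dispersion <= 0)
        stop("'baseMean' and 'dispersion' must be positive")
    n <- length(labels)
    mu <- matrix(baseMean, nrow = nGenes, ncol = n)
    for (d in seq_len(D)) {
        rows <- (d - 1L) * markersPerDomain + seq_len(markersPerDomain)
        mu[rows, labels == doms[d]] <- baseMean * markerFold
    }
    counts <- .withSeed(seed, {
        matrix(stats::rnbinom(nGenes * n, mu = mu, size = 1 / dispersion),
               nrow = nGenes, ncol = n)
    })
    dimnames(counts) <- list(sprintf("gene%d", seq_len(nGenes)),
                             sprintf("spot%d", seq_len(n)))
    counts
}

#' Inject technical dropouts into a true count matrix
#'
#' Zeroes non-zero entries of the ground-truth matrix to emulate technical
#' dropout, recording exactly which entries were zeroed. Biological zeros
#' (entries already zero in the truth) are never flagged, keeping the
#' technical/biological distinction exact.
#'
#' `mode = "uniform"` zeroes each non-zero entry independently with probability
#' `rate`. `mode = "expression_dependent"` zeroes entry v with probability
#' proportional to `exp(-v / decayScale)` (low expression drops out more, as
#' in real SRT), rescaled so the marginal dropout fraction is approximately
#' `rate`; `decayScale` defaults to the median non-zero true value.
#'
#' @param trueMatrix genes x spots non-negative matrix.
#' @param rate target dropout fraction among non-zero entries, in \[0, 1\].
#' @param mode `"uniform"` or `"expression_dependent"`.
#' @param seed integer seed, or `NULL`.
#' @param decayScale decay scale for expression-dependent dropout.
#' @return list with `observed` (matrix after dropout) and `mask` (logical
#'   matrix, `TRUE` where a non-zero true value was zeroed).
#' @examples
#' m <- matrix(rpois(100, 3), 10)
#' dr <- injectDropouts(m, rate = 0.3, seed = 1)
#' mean(dr$mask[m != 0])
#' @export
injectDropouts <- function(trueMatrix, rate = 0.3,
                           mode = c("uniform", "expression_dependent"),
                           seed = NULL, decayScale = NULL) {
    mode <- match.arg(mode)
    if (rate < 0 || rate > 1)
        stop("'rate' must lie in [0, 1]")
    if (any(trueMatrix < 0))
        stop("'trueMatrix' must be non-negative")
    tm <- as.matrix(trueMatrix)
    storage.mode(tm) <- "double"
    nz <- tm != 0
    mask <- matrix(FALSE, nrow(tm), ncol(tm), dimnames = dimnames(tm))
    nzIdx <- which(nz)
    if (length(nzIdx) && rate > 0) {
        p <- if (mode == "uniform") {
            rep(rate, length(nzIdx))
        } else {
            v <- tm[nzIdx]
            if (is.null(decayScale)) decayScale <- stats::median(v)
            w <- exp(-v / decayScale)
            pmin(1, rate * w / mean(w))
        }
        hit <- .withSeed(seed, stats::runif(length(nzIdx)) < p)
        mask[nzIdx[hit]] <- TRUE
    }
    observed <- tm
    observed[mask] <- 0
    list(observed = observed, mask = mask)
}

#' Mask a fraction of non-zero entries for recovery validation
#'
#' Uniformly samples `floor(fraction * nnz)` non-zero entries without
#' replacement, sets them to zero, and records their positions and original
#' values. Used to test whether imputation recovers held-out true values
#' rather than merely reinforcing spatial similarity.
#'
#' @param x genes x spots matrix with at least one non-zero entry.
#' @param fraction fraction of non-zero entries to mask, in (0, 1).
#' @param seed integer seed, or `NULL`.
#' @return list with `masked` (matrix) and `evalMask` (data.frame with
#'   columns `gene`, `spot`, `value` — the original non-zero values).
#' @examples
#' m <- matrix(1:20, 4)
#' mk <- maskNonzero(m, 0.25, seed = 1)
#' nrow(mk$evalMask)
#' @export
maskNonzero <- function(x, fraction, seed = NULL) {
    xm <- as.matrix(x)
    storage.mode(xm) <- "double"
    nzIdx <- which(xm != 0)
    if (!length(nzIdx))
        stop("'x' has no non-zero entries to mask")
    if (fraction <= 0 || fraction >= 1)
        stop("'fraction' must lie in (0, 1)")
    m <- floor(fraction * length(nzIdx))
    if (m < 1L)
        stop("'fraction' = ", fraction, " selects zero entries; increase it")
    sel <- .withSeed(seed, sample(nzIdx, m))
    pos <- arrayInd(sel, dim(xm))
    evalMask <- data.frame(gene = pos[, 1], spot = pos[, 2],
                           value = xm[sel])
    masked <- xm
    masked[sel] <- 0
    list(masked = masked, evalMask = evalMask)
}

#' Simulate a complete synthetic SRT dataset
#'
#' One-stop generator combining [generateDomains()], [generateExpression()]
#' and [injectDropouts()]. The defaults emulate the regime the imputer
#' targets: layered tissue with domain-specific gene programs, count-valued
#' expression, and technical dropout injected on top of true biological zeros.
#'
#' @inheritParams generateDomains
#' @inheritParams generateExpression
#' @param nGenes number of genes.
#' @param dropoutRate dropout fraction among non-zero entries.
#' @param dropoutMode `"uniform"` or `"expression_dependent"`.
#' @param seed integer seed driving the whole simulation.
#' @return a [SpotExperiment-class] with assays `counts` (observed, after
#'   dropout), `trueCounts` (ground truth) and `dropout` (logical mask),
#'   `colData(x)$domain` ground-truth labels, spatial coordinates, and all
#'   generator settings in `metadata(x)$simulation`.
#' @examples
#' se <- simulateSpatialData(nSpots = 100, nGenes = 30, seed = 1)
#' SummarizedExperiment::assayNames(se)
#' @export
simulateSpatialData <- function(nSpots = 2000, nGenes = 200, nDomains = 4,
                                layout = "grid",
                                markersPerDomain = max(1L, floor(0.1 * nGenes)),
                                baseMean = 2, markerFold = 5, dispersion = 1,
                                dropoutRate = 0.3, dropoutMode = "uniform",
                                seed = NULL) {
    params <- list(nSpots = nSpots, nGenes = nGenes, nDomains = nDomains,
                   layout = layout, markersPerDomain = markersPerDomain,
                   baseMean = baseMean, markerFold = markerFold,
                   dispersion = dispersion, dropoutRate = dropoutRate,
                   dropoutMode = dropoutMode, seed = seed)
    res <- .withSeed(seed, {
        dom <- generateDomains(nSpots, layout = layout, nDomains = nDomains,
                               seed = NULL)
        true <- generateExpression(dom$labels, nGenes = nGenes,
                                   markersPerDomain = markersPerDomain,
                                   baseMean = baseMean,
                                   markerFold = markerFold,
                                   dispersion = dispersion, seed = NULL)
        dr <- injectDropouts(true, rate = dropoutRate, mode = dropoutMode,
                             seed = NULL)
        list(dom = dom, true = true, dr = dr)
    })
    se <- SpotExperiment(res$dr$observed, coords = res$dom$coords,
                         domain = res$dom$labels)
    SummarizedExperiment::assay(se, "trueCounts") <- res$true
    SummarizedExperiment::assay(se, "dropout") <- res$dr$mask
    S4Vectors::metadata(se)$simulation <- params
    se
}
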