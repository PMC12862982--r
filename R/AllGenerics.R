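#' @name SpotExperiment-accessors
#' @title Accessors for SpotExperiment
#'
#' @description
#' `spatialCoords()` returns the n_spots x 2 coordinate matrix (or `NULL` for
#' a coordinate-free bundle). `domainLabels()` returns the per-spot
#' ground-truth domain annotation, or `NULL` when absent.
#'
#' @param x a [SpotExperiment-class].
#' @param value replacement value.
#'
#' @return `spatialCoords` returns a numeric matrix or `NULL`;
#'   `domainLabels` returns a vector or `NULL`.
#'
#' @examples
#' se <- simulateSpatialData(nSpots = 64, nGenes = 20, seed = 1)
#' head(spatialCoords(se))
#' table(domainLabels(se))
NULL

#' @rdname SpotExperiment-accessors
#' @export
setGeneric("spatialCoords", function(x) standardGeneric("spatialCoords"))

#' @rdname SpotExperiment-accessors
#' @export
setGeneric("spatialCoords<-", function(x, value)
    standardGeneric("spatialCoords<-"))

#' @rdname SpotExperiment-accessors
#' @export
setGeneric("domainLabels", function(x) standardGeneric("domainLabels"))

#' @rdname SpotExperiment-accessors
#' @export
setGeneric("domainLabels<-", function(x, value)
    standardGeneric("domainLabels<-"))

#' @rdname SpotExperiment-accessors
#' @export
setMethod("spatialCoords", "SpotExperiment", function(x) {
    if (!"spatial" %in% SingleCellExperiment::reducedDimNames(x))
        return(NULL)
    SingleCellExperiment::reducedDim(x, "spatial")
})

#' @rdname SpotExperiment-accessors
#' @export
setMethod("spatialCoords<-", "SpotExperiment", function(x, value) {
    value <- as.matrix(value)
    storage.mode(value) <- "double"
    colnames(value) <- c("x", "y")
    SingleCellExperiment::reducedDim(x, "spatial") <- value
    .checkSpotExperiment(x)
    x
})

#' @rdname SpotExperiment-accessors
#' @export
setMethod("domainLabels", "SpotExperiment", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if (!"domain" %in% colnames(cd)) return(NULL)
    cd$domain
})

#' @rdname SpotExperiment-accessors
#' @export
setMethod("domainLabels<-", "SpotExperiment", function(x, value) {
    SummarizedExperiment::colData(x)$domain <- value
    x
})

#' @importFrom methods show callNextMethod
setMethod("show", "SpotExperiment", function(object) {
    callNextMethod()
    sp <- spatialCoords(object)
    if (is.null(sp)) {
        cat("spatial: <none> (coordinate-free; imputation unavailable)\n")
    } else {
        cat(sprintf("spatial: %d spots, x range [%.3g, %.3g], y range [%.3g, %.3g]\n",
                    nrow(sp), min(sp[, 1]), max(sp[, 1]),
                    min(sp[, 2]), max(sp[, 2])))
    }
    rep <- S4Vectors::metadata(object)$imputation_report
    if (!is.null(rep))
        cat(sprintf("imputation: %d dropouts imputed, %d zeros retained\n",
                    rep@nImputed, rep@nRetainedBiological))
})

#' Normalize, select genes, impute: generics
#'
#' These generics dispatch on plain matrices (genes x spots) and on
#' [SpotExperiment-class] objects; see the method pages for details.
#'
#' @param x matrix or SpotExperiment.
#' @param ... method arguments.
#' @name spamean-generics
NULL

#' @rdname normalizeLog1p
#' @export
setGeneric("normalizeLog1p", function(x, ...) standardGeneric("normalizeLog1p"))

#' @rdname selectHVG
#' @export
setGeneric("selectHVG", function(x, ...) standardGeneric("selectHVG"))

#' @rdname spaMeanImpute
#' @export
setGeneric("spaMeanImpute", function(x, ...) standardGeneric("spaMeanImpute"))

#' @rdname zeroSparsity
#' @export
setGeneric("zeroSparsity", function(x, ...) standardGeneric("zeroSparsity"))
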