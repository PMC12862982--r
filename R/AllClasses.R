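#' SpotExperiment: spatially resolved expression container
#'
#' `SpotExperiment` extends [SingleCellExperiment::SingleCellExperiment] for
#' spatially resolved transcriptomics (SRT) data. Rows are genes, columns are
#' spots (barcoded capture locations). Planar spot coordinates are stored as an
#' n x 2 matrix in `reducedDim(x, "spatial")`, and optional ground-truth domain
#' annotations live in `colData(x)$domain`.
#'
#' The validity contract is what the imputation stage relies on: exactly two
#' finite coordinate columns, one row per spot.
#'
#' @slot ... inherited from `SingleCellExperiment`.
#'
#' @seealso [SpotExperiment()] for construction, [spatialCoords()],
#'   [domainLabels()], [spaMeanImpute()].
#'
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @exportClass SpotExperiment
setClass("SpotExperiment", contains = "SingleCellExperiment")

# Contract check for the spatial slot. Not registered with setValidity():
# the SummarizedExperiment accessor stack routes through updateObject(),
# whose validObject() call would re-enter a registered validity method and
# recurse. The constructor and the coordinate setter enforce it instead.
.checkSpotExperiment <- function(object) {
    msg <- NULL
    if (!"spatial" %in% SingleCellExperiment::reducedDimNames(object))
        return(invisible(object))  # coordinate-free bundle: metrics only
    sp <- SingleCellExperiment::reducedDim(object, "spatial")
    if (ncol(sp) != 2L)
        msg <- c(msg, "'spatial' coordinates must have exactly 2 columns")
    if (nrow(sp) != ncol(object))
        msg <- c(msg, "one coordinate row per spot is required")
    if (anyNA(sp) || any(!is.finite(as.matrix(sp))))
        msg <- c(msg, "'spatial' coordinates must be finite and non-missing")
    if (!is.null(msg))
        stop("invalid SpotExperiment: ", paste(msg, collapse = "; "))
    invisible(object)
}

#' Construct a SpotExperiment
#'
#' @param counts numeric matrix (dense or `Matrix` sparse), genes x spots.
#'   Raw counts go in the `"counts"` assay; [normalizeLog1p()] adds
#'   `"logcounts"`.
#' @param coords numeric matrix or data.frame with n_spots rows and 2 columns
#'   (x, y), or `NULL` for a coordinate-free bundle (metrics only; imputation
#'   refuses it).
#' @param domain optional vector of per-spot ground-truth domain labels.
#' @param ... further arguments passed to
#'   [SingleCellExperiment::SingleCellExperiment()], e.g. `metadata`.
#'
#' @return A [SpotExperiment-class] object.
#'
#' @examples
#' m <- matrix(rpois(50, 2), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
#' xy <- cbind(x = runif(10), y = runif(10))
#' se <- SpotExperiment(m, xy)
#' se
#'
#' @importFrom SingleCellExperiment SingleCellExperiment reducedDim<-
#' @export
SpotExperiment <- function(counts, coords = NULL, domain = NULL, ...) {
    counts <- .asMatrixLike(counts)
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("spot%d", seq_len(ncol(counts)))
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("gene%d", seq_len(nrow(counts)))
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts), ...)
    se <- methods::new("SpotExperiment", sce)
    if (!is.null(coords)) {
        coords <- as.matrix(coords)
        if (ncol(coords) != 2L)
            stop("'coords' must have exactly 2 columns (x, y)")
        if (nrow(coords) != ncol(counts))
            stop("'coords' must have one row per spot (", ncol(counts),
                 "), got ", nrow(coords))
        storage.mode(coords) <- "double"
        colnames(coords) <- c("x", "y")
        rownames(coords) <- colnames(counts)
        SingleCellExperiment::reducedDim(se, "spatial") <- coords
    }
    if (!is.null(domain)) {
        if (length(domain) != ncol(counts))
            stop("'domain' must have one entry per spot")
        SummarizedExperiment::colData(se)$domain <- domain
    }
    .checkSpotExperiment(se)
    se
}

.asMatrixLike <- function(x) {
    if (is.data.frame(x)) x <- as.matrix(x)
    if (!(is.matrix(x) || methods::is(x, "Matrix")))
        stop("expression input must be a matrix or Matrix")
    if (any(x < 0))
        stop("expression values must be non-negative")
    x
}
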