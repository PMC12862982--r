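#' Read a spot-gene bundle from tabular files
#'
#' @description
#' Loads an expression matrix plus aligned spot coordinates (and optional
#' ground-truth labels) from plain-text files:
#'
#' * `matrixPath` — either a MatrixMarket `.mtx` file (genes x spots; gene and
#'   spot identifiers are read from companion files obtained by replacing the
#'   `.mtx` suffix with `_genes.txt` and `_spots.txt`, one id per line), or a
#'   CSV with gene ids in the first column and one column per spot.
#' * `coordsPath` — CSV with columns `spot_id`, `x`, `y` in any row order;
#'   rows are joined to the matrix spot order on `spot_id`.
#' * `labelsPath` — optional CSV with columns `spot_id`, `label`.
#'
#' Spot order is taken from the matrix file; unmatched spot ids are an error
#' naming the first offenders. A bundle without coordinates can be created by
#' passing `coordsPath = NULL` (metrics only; imputation will refuse it).
#'
#' @param matrixPath path to the `.mtx` or `.csv` expression matrix.
#' @param coordsPath path to the coordinates CSV, or `NULL`.
#' @param labelsPath optional path to the labels CSV.
#' @return a [SpotExperiment-class].
#' @export
readTabular <- function(matrixPath, coordsPath, labelsPath = NULL) {
    if (!file.exists(matrixPath))
        stop("matrix file not found: ", matrixPath)
    if (grepl("\\.mtx$", matrixPath)) {
        m <- as.matrix(Matrix::readMM(matrixPath))
        genesFile <- sub("\\.mtx$", "_genes.txt", matrixPath)
        spotsFile <- sub("\\.mtx$", "_spots.txt", matrixPath)
        if (!file.exists(genesFile) || !file.exists(spotsFile))
            stop("MTX input needs companion id files: ", genesFile, " and ",
                 spotsFile)
        rownames(m) <- readLines(genesFile)
        colnames(m) <- readLines(spotsFile)
    } else {
        df <- utils::read.csv(matrixPath, check.names = FALSE)
        m <- as.matrix(df[, -1, drop = FALSE])
        rownames(m) <- as.character(df[[1]])
    }
    coords <- NULL
    if (!is.null(coordsPath)) {
        cdf <- utils::read.csv(coordsPath)
        if (!all(c("spot_id", "x", "y") %in% colnames(cdf)))
            stop("coordinates CSV must have columns spot_id, x, y")
        hit <- match(colnames(m), as.character(cdf$spot_id))
        if (anyNA(hit)) {
            bad <- utils::head(colnames(m)[is.na(hit)], 5)
            stop("spot ids missing from coordinates: ",
                 paste(bad, collapse = ", "))
        }
        coords <- as.matrix(cdf[hit, c("x", "y")])
    }
    domain <- NULL
    if (!is.null(labelsPath)) {
        ldf <- utils::read.csv(labelsPath)
        if (!all(c("spot_id", "label") %in% colnames(ldf)))
            stop("labels CSV must have columns spot_id, label")
        hit <- match(colnames(m), as.character(ldf$spot_id))
        if (anyNA(hit)) {
            bad <- utils::head(colnames(m)[is.na(hit)], 5)
            stop("spot ids missing from labels: ", paste(bad, collapse = ", "))
        }
        domain <- ldf$label[hit]
    }
    SpotExperiment(m, coords = coords, domain = domain)
}

# Atomic write: write to a temp file in the same directory, then rename.
.atomicWrite <- function(path, writer) {
    tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
    on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
    writer(tmp)
    if (!file.rename(tmp, path))
        stop("failed to move temporary file into place: ", path)
    invisible(path)
}

.writeMtxWithIds <- function(m, path) {
    .atomicWrite(path, function(tmp)
        Matrix::writeMM(methods::as(Matrix::Matrix(as.matrix(m) * 1,
                                                   sparse = TRUE),
                                    "generalMatrix"), tmp))
    .atomicWrite(sub("\\.mtx$", "_genes.txt", path), function(tmp)
        writeLines(rownames(m), tmp))
    .atomicWrite(sub("\\.mtx$", "_spots.txt", path), function(tmp)
        writeLines(colnames(m), tmp))
}

#' Write a SpotExperiment bundle to tabular files
#'
#' @description
#' Persists every assay, the coordinates, labels, and the JSON-serializable
#' metadata (simulation parameters, QC and imputation reports) as plain-text
#' files under a common prefix:
#' `<prefix>_<assay>.mtx` (+ `_genes.txt`/`_spots.txt` id files, shared
#' across assays), `<prefix>_coords.csv`, `<prefix>_labels.csv` and
#' `<prefix>_meta.json`. All writes are atomic (temp file + rename), so a
#' failed write never leaves a partial artifact under the final name.
#'
#' The bundle round-trips through [readBundle()] with bit-identical matrix
#' values.
#'
#' @param x a [SpotExperiment-class].
#' @param prefix output path prefix (directories are created as needed).
#' @return invisibly, the character vector of files written.
#' @export
writeBundle <- function(x, prefix) {
    dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
    files <- character()
    anames <- SummarizedExperiment::assayNames(x)
    storage <- list()
    for (a in anames) {
        m <- SummarizedExperiment::assay(x, a)
        storage[[a]] <- storage.mode(as.matrix(m))
        p <- paste0(prefix, "_", a, ".mtx")
        .writeMtxWithIds(as.matrix(m), p)
        files <- c(files, p)
    }
    sp <- spatialCoords(x)
    if (!is.null(sp)) {
        p <- paste0(prefix, "_coords.csv")
        .atomicWrite(p, function(tmp)
            utils::write.csv(data.frame(spot_id = colnames(x),
                                        x = sp[, 1], y = sp[, 2]),
                             tmp, row.names = FALSE))
        files <- c(files, p)
    }
    dl <- domainLabels(x)
    if (!is.null(dl)) {
        p <- paste0(prefix, "_labels.csv")
        .atomicWrite(p, function(tmp)
            utils::write.csv(data.frame(spot_id = colnames(x), label = dl),
                             tmp, row.names = FALSE))
        files <- c(files, p)
    }
    meta <- S4Vectors::metadata(x)
    if (!is.null(meta$imputation_report))
        meta$imputation_report <- as.list(meta$imputation_report)
    p <- paste0(prefix, "_meta.json")
    .atomicWrite(p, function(tmp)
        jsonlite::write_json(list(assays = anames, storage = storage,
                                  metadata = meta),
                             tmp, auto_unbox = TRUE, digits = NA,
                             null = "null", pretty = TRUE))
    files <- c(files, p)
    invisible(files)
}

#' Read a SpotExperiment bundle written by writeBundle()
#'
#' @param prefix the path prefix used by [writeBundle()].
#' @return a [SpotExperiment-class] with all assays, coordinates, labels and
#'   metadata restored (S4 report objects come back as plain lists).
#' @export
readBundle <- function(prefix) {
    metaPath <- paste0(prefix, "_meta.json")
    if (!file.exists(metaPath))
        stop("no bundle found at prefix: ", prefix)
    meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
    anames <- meta$assays
    first <- paste0(prefix, "_", anames[[1]], ".mtx")
    coordsPath <- paste0(prefix, "_coords.csv")
    labelsPath <- paste0(prefix, "_labels.csv")
    se <- readTabular(first,
                      coordsPath = if (file.exists(coordsPath)) coordsPath,
                      labelsPath = if (file.exists(labelsPath)) labelsPath)
    SummarizedExperiment::assayNames(se)[1] <- anames[[1]]
    mode1 <- meta$storage[[anames[[1]]]]
    if (!is.null(mode1) && mode1 != "double") {
        m1 <- SummarizedExperiment::assay(se, 1)
        storage.mode(m1) <- mode1
        SummarizedExperiment::assay(se, 1) <- m1
    }
    for (a in anames[-1]) {
        m <- as.matrix(Matrix::readMM(paste0(prefix, "_", a, ".mtx")))
        dimnames(m) <- dimnames(se)
        mode <- meta$storage[[a]]
        if (!is.null(mode) && mode != "double") storage.mode(m) <- mode
        SummarizedExperiment::assay(se, a) <- m
    }
    md <- meta$metadata
    if (!is.null(md) && length(md))
        S4Vectors::metadata(se) <- md
    se
}
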