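#' Simulate a negative-binomial single-cell count matrix with planted
#' cell types and promoter groups
#'
#' Emulates the structure of a two-promoter-group (e.g. CAG+ vs Hes5+)
#' single-cell experiment over three cell types (RGC, IP, EN): counts are
#' negative-binomial with per-cell lognormal library sizes, each type has
#' a disjoint set of planted marker genes elevated by \code{markerLogFC}
#' (log2 units) in that type, and the two groups differ only in type
#' composition.  Truth labels (type, group, marker assignment) travel in
#' \code{colData}/\code{rowData} so downstream stages can be scored
#' against them.
#'
#' @param nGenes total genes.
#' @param nCellsPerGroup named integer vector of cells per promoter group,
#'   e.g. \code{c(CAG = 384, Hes5 = 731)}.
#' @param typeProportions matrix (groups x types) of type proportions per
#'   group, rows summing to 1; defaults approximate a design in which the
#'   Hes5+ group is dominated by RGC-signature cells while the CAG+ group
#'   is mostly early neurons.
#' @param markersPerType planted marker genes per type (disjoint sets).
#' @param markerLogFC log2 elevation of a marker in its own type.
#' @param nbDispersion negative-binomial dispersion (size = 1/dispersion).
#' @param librarySizeLognormal \code{c(mu, sigma)} of the log library
#'   size.
#' @param seed integer seed.
#' @return a \code{SingleCellExperiment} with assay \code{counts},
#'   \code{colData} columns \code{group} and \code{true_type}, and
#'   \code{rowData} column \code{marker_type} (\code{NA} for
#'   non-markers).
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SummarizedExperiment colData rowData assay
#' @export
simulateCounts <- function(nGenes = 2000,
                           nCellsPerGroup = c(CAG = 150, Hes5 = 300),
                           typeProportions = rbind(
                               CAG = c(RGC = 0.25, IP = 0.25, EN = 0.50),
                               Hes5 = c(RGC = 0.77, IP = 0.15, EN = 0.08)),
                           markersPerType = 40,
                           markerLogFC = 2,
                           nbDispersion = 0.4,
                           librarySizeLognormal = c(log(20000), 0.3),
                           seed = 1L) {
    stopifnot(nGenes > 3 * markersPerType,
              all(abs(rowSums(typeProportions) - 1) < 1e-8),
              nbDispersion > 0,
              all(names(nCellsPerGroup) %in% rownames(typeProportions)))
    types <- colnames(typeProportions)
    set.seed(seed)

    group <- rep(names(nCellsPerGroup), nCellsPerGroup)
    type <- unlist(lapply(names(nCellsPerGroup), function(g) {
        sample(types, nCellsPerGroup[[g]], replace = TRUE,
               prob = typeProportions[g, ])
    }))
    nCells <- length(group)

    # baseline relative abundances; markers come first, by type.  Marker
    # genes are drawn from the expressed part of the abundance
    # distribution: a cell-type marker is by definition a gene robustly
    # detected in its type, so silent genes are not eligible.
    rel <- stats::rgamma(nGenes, shape = 0.5, rate = 1) + 1e-4
    markerType <- rep(NA_character_, nGenes)
    for (i in seq_along(types))
        markerType[((i - 1) * markersPerType + 1):(i * markersPerType)] <-
            types[i]
    isMarker <- !is.na(markerType)
    rel[isMarker] <- stats::rgamma(sum(isMarker), shape = 2, rate = 1) + 0.1
    rel <- rel / sum(rel)

    libSize <- stats::rlnorm(nCells, librarySizeLognormal[1],
                             librarySizeLognormal[2])
    fc <- matrix(1, nGenes, nCells)
    for (tp in types) {
        rows <- which(markerType == tp)
        cols <- which(type == tp)
        if (length(rows) && length(cols)) fc[rows, cols] <- 2^markerLogFC
    }
    # per-cell means: relative abundances x marker fold changes, rescaled
    # so the expected library size matches the drawn one
    base <- rel * fc
    mu <- sweep(base, 2, libSize / colSums(base), "*")
    counts <- matrix(stats::rnbinom(nGenes * nCells, mu = mu,
                                    size = 1 / nbDispersion),
                     nGenes, nCells)
    dimnames(counts) <- list(sprintf("gene_%04d", seq_len(nGenes)),
                             sprintf("cell_%04d", seq_len(nCells)))
    SingleCellExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(group = group, true_type = type,
                                       row.names = colnames(counts)),
        rowData = S4Vectors::DataFrame(marker_type = markerType,
                                       row.names = rownames(counts)))
}

#' Write a count matrix as MatrixMarket plus gene/cell name files
#'
#' @param sce a \code{SingleCellExperiment} (assay \code{counts}).
#' @param dir output directory; files \code{counts.mtx},
#'   \code{genes.txt}, \code{cells.txt} (and \code{cells.csv} with the
#'   column metadata) are written there.
#' @return \code{dir}, invisibly.
#' @export
writeCountsMTX <- function(sce, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    m <- Matrix::Matrix(assay(sce, "counts"), sparse = TRUE)
    Matrix::writeMM(m, file.path(dir, "counts.mtx"))
    writeLines(rownames(sce), file.path(dir, "genes.txt"))
    writeLines(colnames(sce), file.path(dir, "cells.txt"))
    utils::write.csv(as.data.frame(colData(sce)),
                     file.path(dir, "cells.csv"), row.names = TRUE)
    invisible(dir)
}

#' Read a count matrix written by \code{writeCountsMTX}
#'
#' @param dir directory containing \code{counts.mtx}, \code{genes.txt},
#'   \code{cells.txt} and optionally \code{cells.csv}.
#' @return a \code{SingleCellExperiment}.
#' @export
readCountsMTX <- function(dir) {
    m <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
    rownames(m) <- readLines(file.path(dir, "genes.txt"))
    colnames(m) <- readLines(file.path(dir, "cells.txt"))
    cd <- S4Vectors::DataFrame(row.names = colnames(m))
    metaPath <- file.path(dir, "cells.csv")
    if (file.exists(metaPath)) {
        meta <- utils::read.csv(metaPath, row.names = 1)
        cd <- S4Vectors::DataFrame(meta[colnames(m), , drop = FALSE])
    }
    SingleCellExperiment(assays = list(counts = m), colData = cd)
}
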